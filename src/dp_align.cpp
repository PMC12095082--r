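#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int gcd_int(int a, int b) {
  while (b != 0) { int t = a % b; a = b; b = t; }
  return a;
}

struct Step {
  int a, b;
  double sq;                  // sqrt(b/a)
  std::vector<int> off;       // floor(b*d/a), d = 0..a
  std::vector<double> fr;     // frac(b*d/a)
  std::vector<double> w;      // trapezoid weights (0.5 at segment ends)
};

// Exact dynamic program for elastic alignment on the SRSF mesh lattice.
// Finds the piecewise-linear warp gamma minimizing
//   int_0^1 (q1(t) - q2(gamma(t)) * sqrt(gamma'(t)))^2 dt
// over lattice paths with predecessor steps (a, b), 1 <= a,b <= width,
// gcd(a, b) = 1; segment costs by trapezoidal quadrature with q2 evaluated
// by linear interpolation. Returns gamma at every mesh point.
// [[Rcpp::export]]
NumericVector dp_warp(NumericVector q1, NumericVector q2, int width) {
  const int n = q1.size();
  if (q2.size() != n) stop("q1 and q2 must share the same mesh");
  if (n < 3) stop("mesh too small");
  if (width < 1) stop("width must be positive");
  const double h = 1.0 / (n - 1);
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<Step> steps;
  for (int a = 1; a <= width; ++a) {
    for (int b = 1; b <= width; ++b) {
      if (gcd_int(a, b) != 1) continue;
      Step s;
      s.a = a; s.b = b;
      s.sq = std::sqrt((double)b / (double)a);
      s.off.resize(a + 1); s.fr.resize(a + 1); s.w.resize(a + 1);
      for (int d = 0; d <= a; ++d) {
        const double gt = (double)b * d / a;
        s.off[d] = (int)std::floor(gt + 1e-12);
        s.fr[d] = gt - s.off[d];
        s.w[d] = (d == 0 || d == a) ? 0.5 : 1.0;
      }
      steps.push_back(s);
    }
  }

  std::vector<double> E((size_t)n * n, INF);
  std::vector<int> PA((size_t)n * n, 0), PB((size_t)n * n, 0);
  E[0] = 0.0;
  const double *q1p = q1.begin(), *q2p = q2.begin();
  const int m = n - 1;

  for (int i = 1; i < n; ++i) {
    // Lattice nodes a monotone path of slope in [1/width, width] can
    // actually pass through; everything else stays infeasible.
    int jlo = std::max((i + width - 1) / width, m - width * (m - i));
    int jhi = std::min(width * i, m - (m - i + width - 1) / width);
    if (i == m) { jlo = std::min(jlo, m); jhi = m; }
    for (int j = std::max(jlo, 1); j <= jhi; ++j) {
      double best = INF;
      int ba = 0, bb = 0;
      for (size_t si = 0; si < steps.size(); ++si) {
        const Step &s = steps[si];
        const int i0 = i - s.a, j0 = j - s.b;
        if (i0 < 0 || j0 < 0) continue;
        const double prev = E[(size_t)i0 * n + j0];
        if (!std::isfinite(prev)) continue;
        double sum = 0.0;
        for (int d = 0; d <= s.a; ++d) {
          const int gi = j0 + s.off[d];
          const double q2g = (gi >= m) ? q2p[m]
            : (1.0 - s.fr[d]) * q2p[gi] + s.fr[d] * q2p[gi + 1];
          const double diff = q1p[i0 + d] - s.sq * q2g;
          sum += s.w[d] * diff * diff;
        }
        const double c = prev + sum * h;
        if (c < best) { best = c; ba = s.a; bb = s.b; }
      }
      E[(size_t)i * n + j] = best;
      PA[(size_t)i * n + j] = ba;
      PB[(size_t)i * n + j] = bb;
    }
  }

  // Backtrack the optimal lattice path from (n-1, n-1).
  std::vector<int> pi, pj;
  int i = m, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    const int a = PA[(size_t)i * n + j], b = PB[(size_t)i * n + j];
    if (a == 0 && b == 0) stop("dynamic program failed to reach the origin");
    i -= a; j -= b;
    pi.push_back(i); pj.push_back(j);
  }

  // Linear interpolation of the path onto the full mesh.
  NumericVector gam(n);
  for (size_t s = pi.size() - 1; s >= 1; --s) {
    const int i0 = pi[s], j0 = pj[s];
    const int i1 = pi[s - 1], j1 = pj[s - 1];
    for (int k = i0; k <= i1; ++k) {
      gam[k] = (j0 + (double)(j1 - j0) * (k - i0) / (i1 - i0)) * h;
    }
  }
  gam[0] = 0.0;
  gam[n - 1] = 1.0;
  return gam;
}
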