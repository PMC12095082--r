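# SRSF transforms, elastic alignment, and phase distances.
#
# Trajectories are treated as functions of normalized time t in [0, 1]
# (affine map of the 0.25-16 y age span). The square-root slope function
# q(t) = sign(f'(t)) * sqrt(|f'(t)|) turns elastic alignment into an L2
# problem; the phase distance between two curves is the arc length, on the
# unit Hilbert sphere, between the SRSF of the optimal relative warp and
# that of the identity: d = arccos( int_0^1 sqrt(gamma'(t)) dt ).

# Gradient with central differences inside and second-order one-sided
# differences at the ends (first-order endpoints bias the sqrt(gamma')
# quadrature visibly at n = 101).
fd_gradient <- function(f, h) {
  n <- length(f)
  g <- numeric(n)
  g[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * h)
  g[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  g[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h)
  g
}

#' Represent a BMI trajectory as a curve on normalized time
#'
#' Linearly resamples grid values onto a uniform mesh of `n_points` on
#' `[0, 1]`, with ages mapped affinely from `[0.25, 16]`.
#'
#' @param values Trajectory values at `ages`.
#' @param ages Ages in years (default the standard grid).
#' @param n_points Uniform mesh resolution (default 101).
#' @return A `curve`: list with `t` (uniform in `[0, 1]`) and `f`.
#' @export
as_curve <- function(values, ages = standard_grid(), n_points = 101) {
  stopifnot(length(values) == length(ages), n_points >= 3)
  if (any(!is.finite(values))) stop("curve values must be finite")
  t <- seq(0, 1, length.out = n_points)
  f <- approx(normalize_age(ages), values, xout = t, rule = 2)$y
  structure(list(t = t, f = f), class = "curve")
}

#' Square-root slope function of a curve
#'
#' `q(t) = sign(f'(t)) * sqrt(|f'(t)|)` with the derivative taken by finite
#' differences on the uniform mesh.
#'
#' @param curve A `curve` (see [as_curve()]).
#' @return An `srsf`: list with `t` and `q`.
#' @export
to_srsf <- function(curve) {
  n <- length(curve$t)
  if (n < 3) stop("n_points must be at least 3")
  h <- curve$t[2] - curve$t[1]
  fp <- fd_gradient(curve$f, h)
  structure(list(t = curve$t, q = sign(fp) * sqrt(abs(fp))), class = "srsf")
}

#' Optimal warp aligning one SRSF to another
#'
#' Finds the piecewise-linear warp `gamma` minimizing
#' `|| q1 - (q2 o gamma) * sqrt(gamma') ||^2` by exact dynamic programming
#' on the mesh lattice with coprime predecessor steps up to
#' `neighborhood_width` (the standard elastic-FDA search space). Applying
#' the result to the second curve, `f2 o gamma`, aligns it to the first.
#'
#' @param q1,q2 `srsf` objects on the same mesh.
#' @param neighborhood_width Maximum lattice step in either direction
#'   (default 7); larger values allow steeper local warps.
#' @return A `warping_function`.
#' @export
align_pair <- function(q1, q2, neighborhood_width = 7) {
  if (length(q1$t) != length(q2$t) || max(abs(q1$t - q2$t)) > 1e-12) {
    stop("SRSFs must share the same mesh")
  }
  gam <- dp_warp(q1$q, q2$q, as.integer(neighborhood_width))
  warping_function(q1$t, gam)
}

# L2 alignment cost of a given warp; used to sanity-check DP optimality.
warp_cost <- function(q1, q2, warp) {
  h <- q1$t[2] - q1$t[1]
  gp <- pmax(fd_gradient(warp$gamma, h), 0)
  q2g <- approx(q2$t, q2$q, xout = warp$gamma, rule = 2)$y
  integrand <- (q1$q - q2g * sqrt(gp))^2
  h * (sum(integrand) - (integrand[1] + integrand[length(integrand)]) / 2)
}

#' Phase distance carried by a warping function
#'
#' Arc length on the unit sphere between the SRSF of `gamma` and that of
#' the identity warp: `arccos( int_0^1 sqrt(gamma'(t)) dt )`. The derivative
#' is taken by finite differences (negative values from flat segments are
#' truncated at zero) and the integral by the trapezoid rule; the arccos
#' argument is clipped to `[0, 1]` against quadrature overshoot.
#'
#' @param warp A `warping_function`.
#' @return Distance in radians, in `[0, pi/2]`.
#' @export
phase_distance <- function(warp) {
  n <- length(warp$t)
  h <- warp$t[2] - warp$t[1]
  gp <- pmax(fd_gradient(warp$gamma, h), 0)
  s <- sqrt(gp)
  integral <- h * (sum(s) - (s[1] + s[n]) / 2)
  acos(min(max(integral, 0), 1))
}

#' Elastic phase distance between two trajectories
#'
#' Aligns each curve to the other by dynamic programming and returns the
#' average of the two directional phase distances (the DP is directional;
#' averaging yields the symmetric dissimilarity that medoid clustering
#' requires).
#'
#' @param f1,f2 `curve` objects on the same mesh (see [as_curve()]).
#' @param neighborhood_width Passed to [align_pair()].
#' @param symmetrize If `FALSE`, only the `f2`-to-`f1` direction is used.
#' @return Distance in radians, in `[0, pi/2]`.
#' @export
elastic_phase_distance <- function(f1, f2, neighborhood_width = 7,
                                   symmetrize = TRUE) {
  q1 <- to_srsf(f1); q2 <- to_srsf(f2)
  d12 <- phase_distance(align_pair(q1, q2, neighborhood_width))
  if (!symmetrize) return(d12)
  d21 <- phase_distance(align_pair(q2, q1, neighborhood_width))
  (d12 + d21) / 2
}

#' Pairwise elastic phase distance matrix
#'
#' Computes the symmetric matrix of elastic phase distances between all
#' trajectories of a BMI grid (callers stratify by sex before calling, as
#' the analysis does).
#'
#' @param bmi A `bmi_grid` (or plain numeric matrix with one trajectory per
#'   row, on the standard grid).
#' @param n_points Uniform mesh resolution for the SRSF/DP stage.
#' @param neighborhood_width Passed to [align_pair()].
#' @param symmetrize Average the two alignment directions (default).
#' @return Symmetric matrix (radians) with zero diagonal and child ids as
#'   dimnames.
#' @export
pairwise_distance_matrix <- function(bmi, n_points = 101,
                                     neighborhood_width = 7,
                                     symmetrize = TRUE) {
  if (inherits(bmi, "bmi_grid")) {
    values <- bmi$values; ages <- bmi$grid_ages; ids <- bmi$child_ids
  } else {
    values <- as.matrix(bmi); ages <- standard_grid()
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  n <- nrow(values)
  if (n < 2) stop("need at least two trajectories")
  bad <- which(!apply(values, 1, function(r) all(is.finite(r))))
  if (length(bad)) stop("non-finite BMI trajectory for child ", ids[bad[1]])

  srsfs <- lapply(seq_len(n), function(i) {
    to_srsf(as_curve(values[i, ], ages, n_points))
  })
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- phase_distance(align_pair(srsfs[[i]], srsfs[[j]],
                                     neighborhood_width))
      if (symmetrize) {
        d <- (d + phase_distance(align_pair(srsfs[[j]], srsfs[[i]],
                                            neighborhood_width))) / 2
      }
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Align a set of trajectories to a reference curve
#'
#' Each curve `f` is replaced by `f o gamma*`, where `gamma*` is the
#' optimal warp aligning it to `ref` — used, e.g., to align cluster members
#' to their medoid before averaging amplitudes.
#'
#' @param curves List of `curve` objects, or a numeric matrix of grid rows.
#' @param ref The reference `curve` (or grid-value vector).
#' @param n_points Mesh resolution used when inputs are grid rows.
#' @param neighborhood_width Passed to [align_pair()].
#' @return List with `aligned` (matrix, one aligned curve per row, on the
#'   reference mesh) and `warps` (list of `warping_function`).
#' @export
align_to_reference <- function(curves, ref, n_points = 101,
                               neighborhood_width = 7) {
  # Grid rows (34 ages) go through as_curve; rows of other lengths are
  # taken as already uniformly meshed and resampled to n_points.
  row_to_curve <- function(v) {
    if (length(v) == length(standard_grid())) {
      as_curve(v, n_points = n_points)
    } else {
      t <- seq(0, 1, length.out = n_points)
      structure(list(t = t,
                     f = approx(seq(0, 1, length.out = length(v)), v,
                                xout = t)$y),
                class = "curve")
    }
  }
  if (is.matrix(curves)) {
    curves <- lapply(seq_len(nrow(curves)), function(i) row_to_curve(curves[i, ]))
  }
  if (!inherits(ref, "curve")) ref <- row_to_curve(ref)
  qref <- to_srsf(ref)
  out <- lapply(curves, function(cv) {
    gam <- align_pair(qref, to_srsf(cv), neighborhood_width)
    list(f = approx(cv$t, cv$f, xout = gam$gamma, rule = 2)$y, warp = gam)
  })
  list(aligned = do.call(rbind, lapply(out, `[[`, "f")),
       warps = lapply(out, `[[`, "warp"),
       t = ref$t)
}
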