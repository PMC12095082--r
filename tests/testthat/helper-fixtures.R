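# Shared fixtures, all generated in code.

# Matrix of warped template trajectories on the standard grid (no
# measurement path), with true labels attached as an attribute.
warped_template_matrix <- function(n_per_type = 5, warp_strength = 0.3,
                                   seed = 1) {
  set.seed(seed)
  tp <- default_cluster_params()
  g <- standard_grid()
  labels <- rep(seq_along(tp), each = n_per_type)
  rows <- t(vapply(labels, function(l) {
    w <- sample_warping(warp_strength)
    ages <- 0.25 + 15.75 * approx(w$t, w$gamma,
                                  xout = (g - 0.25) / 15.75)$y
    make_template_bmi(tp[[l]], ages)
  }, numeric(length(g))))
  rownames(rows) <- sprintf("S%03d", seq_len(nrow(rows)))
  attr(rows, "labels") <- stats::setNames(labels, rownames(rows))
  rows
}

# Block-structured dissimilarity matrix: small within, large between.
block_dissimilarity <- function(sizes, within = 0.1, between = 1.0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(between, n, n)
  for (b in seq_along(sizes)) D[lab == b, lab == b] <- within
  diag(D) <- 0
  dimnames(D) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  D
}

# Minimal long-format record set for one child passing all selection rules.
passing_child <- function(id = "K1", ages = c(0.3, 1, 4, 8, 12, 16.1),
                          sex = "F") {
  h <- 55 + 8 * ages
  data.frame(child_id = id, sex = sex, age_years = ages,
             height_cm = h, weight_kg = 0.16 * (h / 10)^2,
             stringsAsFactors = FALSE)
}

# Uniform-mesh curve object helper.
mesh_curve <- function(f, n = 101) {
  structure(list(t = seq(0, 1, length.out = n), f = f), class = "curve")
}
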