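# Trajectory timing features and cluster summaries.

test_that("peak and valley detection handles monotone, unimodal, and
           plateau cases", {
  g <- standard_grid()
  up <- find_peaks_valleys(seq_along(g), g)
  expect_length(up$peaks, 0)
  expect_length(up$valleys, 0)

  v <- c(seq(14, 17, length.out = 3), seq(16.5, 13, length.out = 8),
         seq(13.3, 18, length.out = 23))
  pv <- find_peaks_valleys(v, g)
  expect_equal(pv$peaks, 3)
  expect_equal(pv$valleys, 11)

  plateau <- c(10, 12, 14, 15, 15, 14, 13, 12, 11, 10, seq(10.5, 18,
               length.out = 24))
  pp <- find_peaks_valleys(plateau, g)
  expect_equal(pp$peaks[1], 4)  # first index of the 15,15 plateau
})

test_that("feature arithmetic follows the slope and duration definitions", {
  g <- standard_grid()
  v <- rep(15, 34)
  v[1] <- 14; v[2] <- 15.5; v[3] <- 17           # peak 17 at 0.75 y
  v[4:12] <- seq(16.5, 15.0, length.out = 9)     # valley 15.0 at 5.0 y
  v[13:34] <- seq(15.2, 19, length.out = 22)
  f <- trajectory_features(v, g)
  expect_equal(f$age_first_peak, 0.75)
  expect_equal(f$infancy_slope, (17 - 14) / 0.5)
  expect_equal(f$age_first_valley, 5.0)
  expect_equal(f$duration_decrease, 4.25)
  expect_equal(f$childhood_slope, -2 / 4.25)

  inc <- trajectory_features(seq(13, 20, length.out = 34), g)
  expect_equal(inc$n_peaks, 0)
  expect_true(is.na(inc$age_first_peak))
  expect_true(is.na(inc$infancy_slope))
  expect_true(is.na(inc$childhood_slope))

  # peak at the first grid point leaves the infancy slope undefined
  dec <- trajectory_features(c(seq(18, 14, length.out = 10),
                               seq(14.2, 19, length.out = 24)), g)
  expect_true(is.na(dec$infancy_slope))
})

test_that("noise-free Type 1 template yields the textbook landmarks", {
  g <- standard_grid()
  f <- trajectory_features(make_template_bmi(default_cluster_params()$type1,
                                             g), g)
  expect_equal(f$age_first_peak, 0.75)
  expect_equal(f$n_peaks, 1)
  expect_gt(f$age_first_valley, 2)
  expect_lte(f$childhood_slope, 0)
})

test_that("the duration identity holds for every synthetic child", {
  co <- simulate_cohort(sim_config(n_per_cluster = 10, seed = 6))
  out <- process_growth_records(co$records)
  feats <- extract_features(out$bmi)
  both <- !is.na(feats$age_first_peak) & !is.na(feats$age_first_valley)
  expect_gt(sum(both), 0)
  expect_equal(feats$duration_decrease[both],
               feats$age_first_valley[both] - feats$age_first_peak[both])
  expect_true(all(feats$age_first_valley[both] > feats$age_first_peak[both]))
  expect_true(all(feats$childhood_slope[both] <= 0))
})

test_that("cluster summaries use linear-interpolation quartiles and count
           defined values", {
  feats <- data.frame(child_id = c("a", "b", "c"),
                      age_first_peak = c(0.75, 0.75, 1),
                      age_first_valley = c(5, 4, NA),
                      infancy_slope = c(2, 4, 6),
                      childhood_slope = c(-0.5, -0.7, NA),
                      duration_decrease = c(4.25, 3.25, NA),
                      n_peaks = c(1, 1, 2))
  labels <- stats::setNames(c(1, 1, 1), c("a", "b", "c"))
  s <- summarize_features_by_cluster(feats, labels)
  row <- s[s$feature == "infancy_slope", ]
  expect_equal(row$median, 4)
  expect_equal(row$q1, 3)
  expect_equal(row$q3, 5)
  expect_equal(row$n, 3)
  expect_equal(s[s$feature == "age_first_valley", ]$n, 2)

  single <- summarize_features_by_cluster(feats[1, ],
                                          stats::setNames(1, "a"))
  r1 <- single[single$feature == "duration_decrease", ]
  expect_equal(r1$median, 4.25)
  expect_equal(r1$q1, r1$q3)

  all_na <- feats
  all_na$childhood_slope <- NA_real_
  s2 <- summarize_features_by_cluster(all_na, labels)
  expect_equal(s2[s2$feature == "childhood_slope", ]$n, 0)
  expect_true(is.na(s2[s2$feature == "childhood_slope", ]$median))
})

test_that("peak count table caps categories and percentages sum to 100", {
  feats <- data.frame(child_id = letters[1:5], n_peaks = c(0, 1, 2, 3, 4))
  labels <- stats::setNames(rep(1, 5), letters[1:5])
  tab <- peak_count_table(feats, labels, cap = 3)
  expect_equal(tab$n_peaks, 0:3)
  expect_equal(tab$count, c(1L, 1L, 1L, 2L))
  expect_lt(abs(sum(tab$percent) - 100), 0.2)

  # invariance to child ordering
  perm <- c(4, 2, 5, 1, 3)
  tab2 <- peak_count_table(feats[perm, ], labels)
  expect_equal(tab2$count, tab$count)

  ones <- data.frame(child_id = letters[1:10], n_peaks = rep(1, 10))
  t1 <- peak_count_table(ones, stats::setNames(rep(1, 10), letters[1:10]))
  expect_equal(t1$percent, c(0, 100, 0, 0))
})

test_that("aligned cross-sections recover cluster structure", {
  # identical curves: zero-width intervals
  g <- standard_grid()
  tpl <- make_template_bmi(default_cluster_params()$type1, g)
  vals <- rbind(tpl, tpl, tpl)
  rownames(vals) <- c("a", "b", "c")
  bmi <- structure(list(child_ids = c("a", "b", "c"),
                        sex = stats::setNames(rep("F", 3), c("a", "b", "c")),
                        grid_ages = g, values = vals), class = "bmi_grid")
  D <- pairwise_distance_matrix(bmi)
  fit <- pam(D, 2)
  cs <- aligned_cross_sections(bmi, fit)
  big <- cs[cs$n > 1, ]
  expect_equal(big$upper - big$lower, rep(0, nrow(big)), tolerance = 1e-9)

  # mean curve lies within the pointwise envelope of aligned members
  M <- warped_template_matrix(4, warp_strength = 0.2, seed = 9)
  bmi2 <- structure(list(child_ids = rownames(M),
                         sex = stats::setNames(rep("F", nrow(M)),
                                               rownames(M)),
                         grid_ages = g, values = M), class = "bmi_grid")
  D2 <- pairwise_distance_matrix(bmi2)
  fit2 <- pam(D2, 3)
  cs2 <- aligned_cross_sections(bmi2, fit2)
  expect_true(all(cs2$mean >= min(M) - 0.5 & cs2$mean <= max(M) + 0.5))
})

test_that("aligning warped copies to their template recovers its shape", {
  g <- standard_grid()
  tp <- default_cluster_params()
  set.seed(9)
  M <- t(vapply(1:15, function(i) {
    w <- sample_warping(0.3)
    ages <- 0.25 + 15.75 * approx(w$t, w$gamma,
                                  xout = (g - 0.25) / 15.75)$y
    make_template_bmi(tp$type1, ages)
  }, numeric(34)))
  tpl <- make_template_bmi(tp$type1, g)
  al <- align_to_reference(M, as_curve(tpl))
  mean_curve <- approx(al$t, colMeans(al$aligned),
                       xout = (g - 0.25) / 15.75)$y
  expect_lt(max(abs(mean_curve - tpl)), 0.2)
})
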