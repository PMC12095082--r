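# Selection criteria, curve fitting, QC and the BMI grid.

test_that("standard grid matches the published time-point rule", {
  g <- standard_grid()
  expect_length(g, 34)
  expect_equal(g[1], 0.25)
  expect_equal(g[34], 16)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1:4], c(0.25, 0.5, 0.75, 1))
  expect_equal(diff(g[4:34]), rep(0.5, 30))
})

test_that("selection criteria keep and exclude for the stated reasons", {
  ok <- passing_child("A")
  late <- passing_child("B", ages = c(0.6, 1, 4, 8, 12, 16.1))
  gap <- passing_child("C", ages = c(0.3, 1, 5, 10.5, 13, 16.1))
  short <- passing_child("D", ages = c(0.3, 1, 4, 8, 12, 15))
  birth_only <- passing_child("E", ages = c(0.01))
  rec <- rbind(ok, late, gap, short, birth_only)

  rep <- apply_selection_criteria(rec)
  rep <- rep[order(rep$child_id), ]
  expect_equal(rep$status, c("kept", rep("excluded", 4)))
  expect_equal(rep$reason[-1],
               c("late_first", "long_gap", "short_followup",
                 "too_few_points"))

  # order independence
  rep2 <- apply_selection_criteria(rec[sample(nrow(rec)), ])
  expect_equal(rep2[order(rep2$child_id), ]$reason, rep$reason)
})

test_that("series_rule either keeps a child whose weight series passes", {
  child <- passing_child("A")
  child$height_cm[1] <- NA  # height series now starts at 1 y: late_first
  expect_equal(apply_selection_criteria(child)$status, "excluded")
  expect_equal(apply_selection_criteria(child, series_rule = "either")$status,
               "kept")
})

test_that("B-spline fit reproduces cubic polynomials and constants", {
  ages <- seq(0.3, 16, length.out = 12)
  poly <- function(x) 2 + 0.5 * x - 0.03 * x^2 + 0.001 * x^3
  grid <- seq(0.5, 15.5, by = 0.5)
  fit <- fit_growth_spline(ages, poly(ages), grid = grid)
  expect_lt(max(abs(fit$values - poly(grid)) / abs(poly(grid))), 1e-8)

  const <- fit_growth_spline(rep_len(seq(0.3, 16, length.out = 10), 10),
                             rep(100, 10), grid = grid)
  expect_equal(const$values, rep(100, length(grid)), tolerance = 1e-9)

  # determinism: identical observations give identical fits
  f1 <- fit_growth_spline(ages, poly(ages), grid = grid)
  expect_identical(fit$values, f1$values)

  expect_error(fit_growth_spline(ages[1:5], poly(ages[1:5]), grid = grid),
               class = "too_few_points")
})

test_that("linear interpolation passes through observations", {
  f <- fit_growth_linear(c(0.3, 16), c(0.3, 16), grid = 8)
  expect_equal(f$values, 8)
  f2 <- fit_growth_linear(c(0.3, 1, 2), c(0.3, 10, 0), grid = c(1, 1.5))
  expect_equal(f2$values, c(10, 5))
  expect_error(fit_growth_linear(c(1, 2), c(1, 2), grid = 0.5), "outside")
  # clamp rule extends constantly
  f3 <- fit_growth_linear(c(1, 2), c(5, 7), grid = c(0.5, 3), rule = "clamp")
  expect_equal(f3$values, c(5, 7))
})

test_that("decreasing-curve QC flags drops and respects raw corroboration", {
  ages <- seq(0.3, 16, length.out = 12)
  up <- fit_growth_linear(ages, 50 + 8 * ages, grid = standard_grid(),
                          rule = "clamp")
  expect_equal(nrow(qc_decreasing(up, 1.0)), 0)

  dip <- 50 + 8 * ages
  dip[6] <- dip[5] - 3
  dipfit <- fit_growth_linear(ages, dip, grid = standard_grid(),
                              rule = "clamp")
  flags <- qc_decreasing(dipfit, 1.0)
  expect_gte(nrow(flags), 1)
  expect_gt(max(flags$magnitude), 1.0)  # QC mesh need not hit the exact dip

  # a corroborated raw decrease of the same size is not an anomaly
  expect_true(bmiphase:::raw_decrease_exceeds(ages, dip, 2.0))
  expect_false(bmiphase:::raw_decrease_exceeds(ages, 50 + 8 * ages, 2.0))
})

test_that("children are excluded for height anomalies but kept for
           corroborated weight decreases", {
  co <- simulate_cohort(sim_config(n_per_cluster = 2, warp_strength = 0,
                                   amplitude_sd = 0, height_noise_sd = 0,
                                   weight_noise_sd = 0, visit_jitter_sd = 0,
                                   seed = 3))
  rec <- co$records
  # inject a genuine 6 kg weight dip into one child's raw data (well below
  # the running maximum even on this rising curve)
  i <- which(rec$child_id == "C001" & abs(rec$age_years - 8) < 0.26)[1]
  rec$weight_kg[i] <- rec$weight_kg[i] - 6
  # inject an implausible 8 cm height drop into another child
  j <- which(rec$child_id == "C003" & abs(rec$age_years - 8) < 0.26)[1]
  rec$height_cm[j] <- rec$height_cm[j] - 8

  out <- process_growth_records(rec, mode = "linear")
  sel <- out$selection
  expect_equal(sel$status[sel$child_id == "C001"], "kept")
  expect_equal(sel$status[sel$child_id == "C003"], "excluded")
  expect_equal(sel$reason[sel$child_id == "C003"], "qc_anomaly")
})

test_that("BMI combines fitted height and weight correctly", {
  mk <- function(v) structure(list(grid_ages = 1:2, values = v),
                              class = "growth_fit")
  expect_equal(build_bmi_grid(mk(c(100, 160)), mk(c(16, 51.2))),
               c(16, 20))
  base <- build_bmi_grid(mk(c(100, 160)), mk(c(16, 51.2)))
  expect_equal(build_bmi_grid(mk(c(100, 160)), mk(2 * c(16, 51.2))),
               2 * base)
  expect_error(build_bmi_grid(mk(c(-1, 160)), mk(c(16, 51.2))),
               "nonpositive")
})

test_that("spline and linear modes agree when data are exactly cubic at the
           grid ages", {
  g <- standard_grid()
  poly <- function(x) 60 + 6 * x - 0.1 * x^2 + 0.002 * x^3
  rec <- data.frame(child_id = "P", sex = "F", age_years = g,
                    height_cm = poly(g), weight_kg = 0.2 * poly(g) - 2)
  # first age 0.25 > birth_epsilon, max 16: passes selection
  outb <- process_growth_records(rec, mode = "bspline")
  outl <- process_growth_records(rec, mode = "linear")
  expect_equal(outb$bmi$values, outl$bmi$values, tolerance = 1e-6)
})

test_that("every BMI grid row is finite, positive, and 34 long", {
  co <- simulate_cohort(sim_config(n_per_cluster = 4, seed = 8))
  out <- process_growth_records(co$records)
  expect_equal(ncol(out$bmi$values), 34)
  expect_true(all(is.finite(out$bmi$values)))
  expect_true(all(out$bmi$values > 0))
})
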