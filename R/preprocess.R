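# Selection criteria, per-child growth-curve fitting, QC, and the BMI grid.

#' Apply measurement-density selection criteria
#'
#' A child's measurement series passes when, after discarding birth measures
#' (age <= `birth_epsilon`): the earliest measurement is before 6 months of
#' age, the last is at or after 16 years, and no gap between consecutive
#' measurements reaches 5 years. Height and weight series are screened
#' separately; by default a child is kept only if both series pass
#' (`series_rule = "both"`). The first failing rule, in the order
#' late_first, short_followup, long_gap, is recorded; a series with no
#' non-birth measurements gives too_few_points.
#'
#' @param records Long data.frame with columns child_id, age_years,
#'   height_cm, weight_kg (missing measurements as NA).
#' @param birth_epsilon Age (years) at or below which a measurement counts
#'   as a birth measure; default two weeks.
#' @param series_rule "both" (default) or "either": how the per-series
#'   verdicts combine into the child-level decision.
#' @return A `selection_report`: data.frame with columns child_id, status
#'   ("kept"/"excluded") and reason (NA when kept).
#' @export
apply_selection_criteria <- function(records, birth_epsilon = 14 / 365.25,
                                     series_rule = c("both", "either")) {
  series_rule <- match.arg(series_rule)
  stopifnot(nrow(records) > 0)
  ids <- unique(records$child_id)

  check_series <- function(ages) {
    ages <- sort(ages[!is.na(ages) & ages > birth_epsilon])
    if (length(ages) == 0) return("too_few_points")
    if (ages[1] >= 0.5) return("late_first")
    if (ages[length(ages)] < 16) return("short_followup")
    if (length(ages) > 1 && any(diff(ages) >= 5)) return("long_gap")
    NA_character_
  }

  out <- lapply(ids, function(id) {
    rows <- records[records$child_id == id, ]
    rh <- check_series(rows$age_years[!is.na(rows$height_cm)])
    rw <- check_series(rows$age_years[!is.na(rows$weight_kg)])
    fails <- c(height = rh, weight = rw)
    fails <- fails[!is.na(fails)]
    excluded <- if (series_rule == "both") length(fails) > 0 else length(fails) == 2
    reason <- NA_character_
    if (excluded) {
      order_rules <- c("late_first", "short_followup", "long_gap",
                       "too_few_points")
      reason <- order_rules[min(match(fails, order_rules))]
    }
    data.frame(child_id = id,
               status = if (excluded) "excluded" else "kept",
               reason = reason, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, out)
  class(report) <- c("selection_report", "data.frame")
  report
}

# Average duplicated measurement ages so each age appears once per series.
dedupe_series <- function(ages, values) {
  keep <- !is.na(ages) & !is.na(values)
  ages <- ages[keep]; values <- values[keep]
  o <- order(ages)
  ages <- ages[o]; values <- values[o]
  if (anyDuplicated(ages)) {
    values <- tapply(values, ages, mean)
    ages <- as.numeric(names(values))
    values <- unname(values)
  }
  list(ages = ages, values = values)
}

#' Fit a least-squares B-spline growth curve
#'
#' Fits a regression B-spline to one child's measurement series, with knots
#' at the child's minimum and maximum observed ages plus fixed interior
#' knots at 3, 12, 48, 96 and 144 months (interior knots outside the child's
#' observed span are dropped), and evaluates it at `grid` ages.
#'
#' @param ages,values Observed measurement series (years; cm or kg).
#' @param degree Spline degree (default 3). If the design matrix is rank
#'   deficient the fit is retried once at `degree - 1`.
#' @param interior_knots_months Fixed interior knot positions in months.
#' @param grid Evaluation ages in years.
#' @param rule "error": grid ages outside the observed span are an error;
#'   "clamp": they are evaluated at the nearest observed endpoint.
#' @param child_id,measure Carried into the result for bookkeeping.
#' @return A `growth_fit`: grid ages and fitted values plus the spline
#'   representation (knots, coefficients, degree, observed range).
#' @export
fit_growth_spline <- function(ages, values, degree = 3,
                              interior_knots_months = c(3, 12, 48, 96, 144),
                              grid = standard_grid(),
                              rule = c("error", "clamp"),
                              child_id = NA_character_,
                              measure = NA_character_) {
  rule <- match.arg(rule)
  s <- dedupe_series(ages, values)
  amin <- min(s$ages); amax <- max(s$ages)
  interior <- sort(interior_knots_months / 12)
  interior <- interior[interior > amin & interior < amax]

  fit_once <- function(deg) {
    if (length(s$ages) < deg + 1 + length(interior)) {
      stop(structure(class = c("too_few_points", "error", "condition"),
                     list(message = sprintf(
                       "need >= %d observations for degree-%d fit with %d interior knots, have %d",
                       deg + 1 + length(interior), deg, length(interior),
                       length(s$ages)), call = sys.call(-1))))
    }
    knots <- c(rep(amin, deg + 1), interior, rep(amax, deg + 1))
    basis <- splines::splineDesign(knots, s$ages, ord = deg + 1)
    dec <- qr(basis)
    if (dec$rank < ncol(basis)) return(NULL)
    coef <- qr.coef(dec, s$values)
    list(knots = knots, coef = coef, degree = deg)
  }
  mod <- fit_once(degree)
  if (is.null(mod) && degree > 1) mod <- fit_once(degree - 1)
  if (is.null(mod)) stop("rank-deficient spline design; cannot fit series")

  fit <- structure(list(child_id = child_id, measure = measure,
                        grid_ages = grid, values = NULL, qc_flags = NULL,
                        method = "bspline", knots = mod$knots,
                        coef = mod$coef, degree = mod$degree,
                        range = c(amin, amax),
                        obs_ages = s$ages, obs_values = s$values),
                   class = "growth_fit")
  fit$values <- predict_growth_fit(fit, grid, rule = rule)
  fit
}

#' Fit a piecewise-linear growth curve (sensitivity mode)
#'
#' Linear interpolation through the (deduplicated) observed points,
#' evaluated at `grid` ages.
#'
#' @inheritParams fit_growth_spline
#' @return A `growth_fit` with `method = "linear"`.
#' @export
fit_growth_linear <- function(ages, values, grid = standard_grid(),
                              rule = c("error", "clamp"),
                              child_id = NA_character_,
                              measure = NA_character_) {
  rule <- match.arg(rule)
  s <- dedupe_series(ages, values)
  if (length(s$ages) < 2) {
    stop(structure(class = c("too_few_points", "error", "condition"),
                   list(message = "need at least 2 observations for linear interpolation",
                        call = sys.call(-1))))
  }
  fit <- structure(list(child_id = child_id, measure = measure,
                        grid_ages = grid, values = NULL, qc_flags = NULL,
                        method = "linear", range = range(s$ages),
                        obs_ages = s$ages, obs_values = s$values),
                   class = "growth_fit")
  fit$values <- predict_growth_fit(fit, grid, rule = rule)
  fit
}

#' Evaluate a fitted growth curve at arbitrary ages
#'
#' @param fit A `growth_fit`.
#' @param ages Ages in years.
#' @param rule "error" or "clamp" (constant extension beyond the observed
#'   span).
#' @return Fitted values at `ages`.
#' @export
predict_growth_fit <- function(fit, ages, rule = c("error", "clamp")) {
  rule <- match.arg(rule)
  lo <- fit$range[1]; hi <- fit$range[2]
  outside <- ages < lo - 1e-9 | ages > hi + 1e-9
  if (any(outside)) {
    if (rule == "error") {
      stop("grid ages outside the observed range [", signif(lo, 4), ", ",
           signif(hi, 4), "]")
    }
    ages <- pmin(pmax(ages, lo), hi)
  }
  if (fit$method == "linear") {
    approx(fit$obs_ages, fit$obs_values, xout = ages, rule = 2)$y
  } else {
    basis <- splines::splineDesign(fit$knots, ages, ord = fit$degree + 1)
    drop(basis %*% fit$coef)
  }
}

#' Flag implausible decreases in a fitted growth curve
#'
#' Evaluates the fitted curve on a dense mesh (the standard grid refined
#' `refine`-fold) and flags every maximal interval where the fitted value
#' falls more than `threshold` below its running maximum — the screen used
#' to catch spline artefacts such as a fitted height that shrinks.
#'
#' @param fit A `growth_fit`.
#' @param threshold Drop threshold in the measure's units (1 cm for height,
#'   2 kg for weight in the default pipeline).
#' @param refine Mesh refinement factor over the standard grid.
#' @return data.frame with columns start_age, end_age, magnitude (max drop
#'   below the running maximum in the interval); zero rows when clean.
#' @export
qc_decreasing <- function(fit, threshold, refine = 4L) {
  g <- standard_grid()
  mesh <- unique(sort(unlist(lapply(seq_len(length(g) - 1), function(i) {
    seq(g[i], g[i + 1], length.out = refine + 1)
  }))))
  v <- predict_growth_fit(fit, mesh, rule = "clamp")
  drop_below <- cummax(v) - v
  bad <- drop_below > threshold
  if (!any(bad)) {
    return(data.frame(start_age = numeric(0), end_age = numeric(0),
                      magnitude = numeric(0)))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start_age = mesh[starts[idx]], end_age = mesh[ends[idx]],
             magnitude = vapply(idx, function(k) {
               max(drop_below[starts[k]:ends[k]])
             }, numeric(1)))
}

# Does the raw series itself drop by at least `threshold` from its running
# maximum? Used to forgive weight QC flags corroborated by the data.
raw_decrease_exceeds <- function(ages, values, threshold) {
  s <- dedupe_series(ages, values)
  if (length(s$values) < 2) return(FALSE)
  max(cummax(s$values) - s$values) >= threshold
}

#' Combine fitted height and weight curves into a BMI row
#'
#' @param height,weight `growth_fit` objects on the same grid (cm, kg).
#' @return BMI values `weight / (height/100)^2` in kg/m^2.
#' @export
build_bmi_grid <- function(height, weight) {
  stopifnot(length(height$grid_ages) == length(weight$grid_ages))
  if (any(height$values <= 0)) stop("nonpositive fitted height")
  weight$values / (height$values / 100)^2
}

#' Preprocess growth records into a BMI grid
#'
#' Runs the full preprocessing stage: selection criteria, per-child height
#' and weight curve fitting (B-spline or linear sensitivity mode), the
#' decreasing-curve QC screen (height flags exclude; weight flags exclude
#' only when the raw observations show no corresponding decrease), and BMI
#' evaluation on the standard 34-point grid.
#'
#' @param records Long data.frame (child_id, sex, age_years, height_cm,
#'   weight_kg).
#' @param mode "bspline" (default) or "linear".
#' @param degree Spline degree.
#' @param interior_knots_months Interior knots in months.
#' @param birth_epsilon,series_rule Passed to [apply_selection_criteria()].
#' @param height_drop_cm,weight_drop_kg QC drop thresholds.
#' @return List with `bmi` (a `bmi_grid`: child_ids, sex, grid_ages, values
#'   matrix), `selection` (a `selection_report` including qc_anomaly and
#'   too_few_points exclusions) and `qc` (per-child flag table).
#' @export
process_growth_records <- function(records, mode = c("bspline", "linear"),
                                   degree = 3,
                                   interior_knots_months = c(3, 12, 48, 96, 144),
                                   birth_epsilon = 14 / 365.25,
                                   series_rule = "both",
                                   height_drop_cm = 1.0,
                                   weight_drop_kg = 2.0) {
  mode <- match.arg(mode)
  selection <- apply_selection_criteria(records, birth_epsilon, series_rule)
  kept <- selection$child_id[selection$status == "kept"]

  grid <- standard_grid()
  rows <- list(); sexes <- character(0); qc_rows <- list()
  for (id in kept) {
    child <- records[records$child_id == id, ]
    fit_series <- function(values, measure) {
      keep <- !is.na(values) & child$age_years > birth_epsilon
      if (mode == "bspline") {
        fit_growth_spline(child$age_years[keep], values[keep],
                          degree = degree,
                          interior_knots_months = interior_knots_months,
                          grid = grid, rule = "clamp",
                          child_id = id, measure = measure)
      } else {
        fit_growth_linear(child$age_years[keep], values[keep], grid = grid,
                          rule = "clamp", child_id = id, measure = measure)
      }
    }
    hfit <- try(fit_series(child$height_cm, "height"), silent = TRUE)
    wfit <- try(fit_series(child$weight_kg, "weight"), silent = TRUE)
    if (inherits(hfit, "try-error") || inherits(wfit, "try-error")) {
      selection$status[selection$child_id == id] <- "excluded"
      selection$reason[selection$child_id == id] <- "too_few_points"
      next
    }
    hflags <- qc_decreasing(hfit, height_drop_cm)
    wflags <- qc_decreasing(wfit, weight_drop_kg)
    if (nrow(hflags)) {
      qc_rows[[length(qc_rows) + 1]] <-
        cbind(child_id = id, measure = "height", hflags, excluded = TRUE)
    }
    exclude_w <- FALSE
    if (nrow(wflags)) {
      corroborated <- raw_decrease_exceeds(
        child$age_years[!is.na(child$weight_kg)],
        child$weight_kg[!is.na(child$weight_kg)], weight_drop_kg)
      exclude_w <- !corroborated
      qc_rows[[length(qc_rows) + 1]] <-
        cbind(child_id = id, measure = "weight", wflags, excluded = exclude_w)
    }
    if (nrow(hflags) || exclude_w) {
      selection$status[selection$child_id == id] <- "excluded"
      selection$reason[selection$child_id == id] <- "qc_anomaly"
      next
    }
    rows[[id]] <- build_bmi_grid(hfit, wfit)
    sexes <- c(sexes, child$sex[1])
  }
  kept_ids <- names(rows)
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(grid))
  rownames(values) <- kept_ids
  bmi <- structure(list(child_ids = kept_ids, sex = setNames(sexes, kept_ids),
                        grid_ages = grid, values = values),
                   class = "bmi_grid")
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(child_id = character(0), measure = character(0),
               start_age = numeric(0), end_age = numeric(0),
               magnitude = numeric(0), excluded = logical(0))
  list(bmi = bmi, selection = selection, qc = qc)
}

#' @export
print.bmi_grid <- function(x, ...) {
  cat("BMI grid:", nrow(x$values), "children x", ncol(x$values),
      "ages (", x$grid_ages[1], "-", x$grid_ages[length(x$grid_ages)],
      "years )\n")
  invisible(x)
}
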