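# Timing-related trajectory features: infancy peak, adiposity rebound,
# slopes, peak counts, cluster summaries, and aligned cross-sections.

#' Locate peaks and valleys on the standard grid
#'
#' Runs of equal values are collapsed to their first index; a collapsed
#' interior point is a peak when both collapsed neighbours are strictly
#' lower and a valley when both are strictly higher. Grid endpoints are
#' never peaks or valleys.
#'
#' @param values Trajectory values on the grid.
#' @param ages Grid ages (default [standard_grid()]).
#' @return List with integer vectors `peaks` and `valleys` (indices into
#'   `values`, at the first index of any plateau).
#' @export
find_peaks_valleys <- function(values, ages = standard_grid()) {
  stopifnot(length(values) == length(ages))
  r <- rle(values)
  first_idx <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  v <- r$values
  m <- length(v)
  peaks <- integer(0); valleys <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (v[i] > v[i - 1] && v[i] > v[i + 1]) peaks <- c(peaks, first_idx[i])
      if (v[i] < v[i - 1] && v[i] < v[i + 1]) valleys <- c(valleys, first_idx[i])
    }
  }
  list(peaks = peaks, valleys = valleys)
}

#' Timing features of one BMI trajectory
#'
#' Extracts the timing landmarks used to characterize maturational
#' patterns: age at the first peak (infancy peak), age at the first valley
#' after that peak (adiposity rebound), the infancy slope (average BMI rate
#' of change from 3 months to the first peak), the childhood slope (from
#' first peak to first valley), the duration of the childhood BMI decrease,
#' and the total number of peaks. Features whose defining landmarks are
#' absent — or whose denominator would vanish (a first peak at 3 months) —
#' are `NA`.
#'
#' @param values Trajectory values on the grid.
#' @param ages Grid ages.
#' @return One-row data.frame: age_first_peak, age_first_valley,
#'   infancy_slope, childhood_slope, duration_decrease, n_peaks.
#' @export
trajectory_features <- function(values, ages = standard_grid()) {
  pv <- find_peaks_valleys(values, ages)
  age_peak <- if (length(pv$peaks)) ages[pv$peaks[1]] else NA_real_
  valley_after <- if (length(pv$peaks)) {
    pv$valleys[pv$valleys > pv$peaks[1]]
  } else integer(0)
  age_valley <- if (length(valley_after)) ages[valley_after[1]] else NA_real_

  infancy_slope <- NA_real_
  if (!is.na(age_peak) && age_peak > ages[1]) {
    infancy_slope <- (values[pv$peaks[1]] - values[1]) / (age_peak - ages[1])
  }
  childhood_slope <- NA_real_
  duration <- NA_real_
  if (!is.na(age_peak) && !is.na(age_valley)) {
    duration <- age_valley - age_peak
    childhood_slope <- (values[valley_after[1]] - values[pv$peaks[1]]) / duration
  }
  data.frame(age_first_peak = age_peak, age_first_valley = age_valley,
             infancy_slope = infancy_slope, childhood_slope = childhood_slope,
             duration_decrease = duration, n_peaks = length(pv$peaks))
}

#' Timing features for every trajectory in a BMI grid
#'
#' @param bmi A `bmi_grid` (or matrix of grid rows with ids as rownames).
#' @return data.frame with one row per child (child_id first).
#' @export
extract_features <- function(bmi) {
  if (inherits(bmi, "bmi_grid")) {
    values <- bmi$values; ages <- bmi$grid_ages; ids <- bmi$child_ids
  } else {
    values <- as.matrix(bmi); ages <- standard_grid()
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  feats <- do.call(rbind, lapply(seq_len(nrow(values)), function(i) {
    trajectory_features(values[i, ], ages)
  }))
  cbind(data.frame(child_id = ids, stringsAsFactors = FALSE), feats)
}

#' Cluster-wise feature summaries (median and quartiles)
#'
#' Per cluster and feature: median, first and third quartile (linear
#' interpolation convention), and `n`, the number of children for whom the
#' feature is defined — so `n` varies between features within a cluster.
#'
#' @param features data.frame from [extract_features()].
#' @param labels Named cluster labels covering `features$child_id`.
#' @param sex Optional named sex vector; when supplied, summaries are
#'   additionally stratified by sex.
#' @return Long data.frame: (sex,) cluster, feature, median, q1, q3, n.
#' @export
summarize_features_by_cluster <- function(features, labels, sex = NULL) {
  stopifnot(all(features$child_id %in% names(labels)))
  labels <- labels[features$child_id]
  if (any(table(labels) == 0)) stop("empty cluster")
  strata <- if (is.null(sex)) rep("all", nrow(features)) else
    unname(sex[features$child_id])
  feat_cols <- c("age_first_peak", "age_first_valley", "infancy_slope",
                 "childhood_slope", "duration_decrease")
  out <- list()
  for (sx in unique(strata)) {
    for (cl in sort(unique(labels))) {
      sel <- strata == sx & labels == cl
      for (fc in feat_cols) {
        x <- features[[fc]][sel]
        x <- x[!is.na(x)]
        q <- if (length(x)) quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
             else rep(NA_real_, 3)
        out[[length(out) + 1]] <- data.frame(
          sex = sx, cluster = cl, feature = fc,
          median = q[2], q1 = q[1], q3 = q[3], n = length(x))
      }
    }
  }
  do.call(rbind, out)
}

#' Peak-count contingency table by cluster
#'
#' Counts children per (cluster, number-of-peaks) category, with counts at
#' or above `cap` pooled into the top category, and the within-cluster
#' percentages.
#'
#' @param features data.frame from [extract_features()].
#' @param labels Named cluster labels.
#' @param cap Pooling cap for the peak count (default 3).
#' @return data.frame: cluster, n_peaks (0..cap), count, percent.
#' @export
peak_count_table <- function(features, labels, cap = 3L) {
  labels <- labels[features$child_id]
  np <- pmin(features$n_peaks, cap)
  out <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    counts <- vapply(0:cap, function(p) sum(np[sel] == p), integer(1))
    out[[length(out) + 1]] <- data.frame(
      cluster = cl, n_peaks = 0:cap, count = counts,
      percent = round(100 * counts / sum(sel), 1))
  }
  do.call(rbind, out)
}

#' Aligned cross-sectional cluster means with confidence intervals
#'
#' Aligns each cluster's trajectories to the cluster medoid (see
#' [align_to_reference()]) and returns, per cluster and grid age, the mean
#' aligned BMI with a normal-approximation 95% interval
#' (`mean +/- 1.96 * sd / sqrt(n)`). Singleton clusters return the mean
#' with `NA` bounds.
#'
#' @param bmi A `bmi_grid`.
#' @param assignment A `pam_clustering` over the same children.
#' @param n_points Mesh resolution for alignment.
#' @return data.frame: cluster, age, mean, lower, upper, n.
#' @export
aligned_cross_sections <- function(bmi, assignment, n_points = 101) {
  stopifnot(inherits(bmi, "bmi_grid"))
  labels <- assignment$labels[bmi$child_ids]
  out <- list()
  for (cl in seq_len(assignment$k)) {
    members <- which(labels == cl)
    ref_row <- bmi$values[assignment$medoid_idx[cl], ]
    al <- align_to_reference(bmi$values[members, , drop = FALSE],
                             as_curve(ref_row, bmi$grid_ages, n_points),
                             n_points = n_points)
    # back to the standard grid ages
    tgrid <- normalize_age(bmi$grid_ages)
    vals <- t(apply(al$aligned, 1, function(f) {
      approx(al$t, f, xout = tgrid, rule = 2)$y
    }))
    m <- colMeans(vals)
    n_cl <- length(members)
    if (n_cl > 1) {
      se <- apply(vals, 2, sd) / sqrt(n_cl)
      lower <- m - 1.96 * se
      upper <- m + 1.96 * se
    } else {
      lower <- upper <- rep(NA_real_, length(m))
    }
    out[[cl]] <- data.frame(cluster = cl, age = bmi$grid_ages, mean = m,
                            lower = lower, upper = upper, n = n_cl)
  }
  do.call(rbind, out)
}
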