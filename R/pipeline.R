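# End-to-end orchestration: simulate, preprocess, distances, cluster,
# features; YAML config, per-stage outputs, and a run manifest.

#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages; any subset can be overridden
#' from a YAML file via [read_pipeline_config()].
#'
#' @param seed Global seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    preprocess = list(mode = "bspline", degree = 3,
                      interior_knots_months = c(3, 12, 48, 96, 144),
                      birth_epsilon = 14 / 365.25, series_rule = "both",
                      height_drop_cm = 1.0, weight_drop_kg = 2.0),
    elastic = list(n_points = 101, neighborhood_width = 7, symmetrize = TRUE),
    cluster = list(kmin = 2, kmax = 10, k_override = NULL,
                   stratify_by_sex = TRUE),
    simulate = list(n_per_cluster = 20, warp_strength = 0.3,
                    amplitude_sd = 0.05, height_noise_sd = 0.5,
                    weight_noise_sd = 0.3, visit_jitter_sd = 0.05)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file path.
#' @param seed Fallback seed when the file sets none.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  merge_lists(default_pipeline_config(seed), user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_to_sim_config <- function(config) {
  s <- config$simulate
  sim_config(n_per_cluster = s$n_per_cluster,
             warp_strength = s$warp_strength,
             amplitude_sd = s$amplitude_sd,
             height_noise_sd = s$height_noise_sd,
             weight_noise_sd = s$weight_noise_sd,
             visit_jitter_sd = s$visit_jitter_sd,
             seed = config$seed)
}

#' Simulate a cohort and write its files
#'
#' Wraps [simulate_cohort()] + [write_cohort()] for the configured
#' simulation block.
#'
#' @param config Pipeline configuration (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the generated `synthetic_cohort`.
#' @export
run_simulate <- function(config = default_pipeline_config(), out_dir) {
  cohort <- simulate_cohort(config_to_sim_config(config))
  write_cohort(cohort, out_dir)
  message("simulate: ", length(cohort$true_labels), " children written to ",
          out_dir, " (seed ", config$seed, ")")
  invisible(cohort)
}

#' Run the full trajectory-clustering pipeline
#'
#' Stages per stratum: selection and QC, curve fitting, BMI grid, pairwise
#' phase distances, silhouette-guided PAM, timing features and cluster
#' summaries, heatmap ordering. Strata are the sexes by default
#' (`cluster$stratify_by_sex`); with stratification off all children are
#' pooled into one stratum.
#'
#' @param records Long measurement data.frame, or a path to a
#'   measurements CSV (child_id, sex, age_years, height_cm, weight_kg).
#' @param config Pipeline configuration.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as CSV along with a `manifest.yaml`.
#' @return List with `selection`, `qc`, and per-stratum results (`bmi`,
#'   `distances`, `selection` of k, `assignment`, `features`, `summary`,
#'   `peak_table`, `heatmap_order`, `silhouette_table`).
#' @export
run_pipeline <- function(records, config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(records)) {
    records <- read.csv(records, stringsAsFactors = FALSE)
  }
  pp <- config$preprocess
  prep <- process_growth_records(
    records, mode = pp$mode, degree = pp$degree,
    interior_knots_months = pp$interior_knots_months,
    birth_epsilon = pp$birth_epsilon, series_rule = pp$series_rule,
    height_drop_cm = pp$height_drop_cm, weight_drop_kg = pp$weight_drop_kg)
  bmi_all <- prep$bmi
  if (length(bmi_all$child_ids) == 0) stop("preprocess: no children passed selection")
  message("preprocess: ", length(bmi_all$child_ids), " of ",
          length(unique(records$child_id)), " children kept")

  strata <- if (isTRUE(config$cluster$stratify_by_sex)) {
    split(bmi_all$child_ids, bmi_all$sex)
  } else {
    list(all = bmi_all$child_ids)
  }

  results <- list()
  for (sx in names(strata)) {
    ids <- strata[[sx]]
    if (length(ids) < max(3, config$cluster$kmin + 1)) {
      warning("stratum '", sx, "' has too few children (", length(ids),
              "); skipped")
      next
    }
    bmi <- structure(list(child_ids = ids,
                          sex = bmi_all$sex[ids],
                          grid_ages = bmi_all$grid_ages,
                          values = bmi_all$values[ids, , drop = FALSE]),
                     class = "bmi_grid")
    el <- config$elastic
    D <- pairwise_distance_matrix(bmi, n_points = el$n_points,
                                  neighborhood_width = el$neighborhood_width,
                                  symmetrize = el$symmetrize)
    ko <- config$cluster$k_override
    if (is.list(ko)) ko <- ko[[sx]]
    sel <- select_k(D, kmin = config$cluster$kmin,
                    kmax = config$cluster$kmax, k_override = ko)
    assignment <- sel$assignment
    message("cluster[", sx, "]: k = ", sel$k, ", sizes ",
            paste(tabulate(assignment$labels, sel$k), collapse = "/"),
            ", avg silhouette ", signif(assignment$avg_silhouette, 3))
    feats <- extract_features(bmi)
    results[[sx]] <- list(
      bmi = bmi, distances = D, k = sel$k,
      silhouette_table = sel$table, assignment = assignment,
      features = feats,
      summary = summarize_features_by_cluster(feats, assignment$labels),
      peak_table = peak_count_table(feats, assignment$labels),
      heatmap_order = order_for_heatmap(D, assignment))
  }
  out <- list(selection = prep$selection, qc = prep$qc, strata = results,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$selection, file.path(out_dir, "selection_report.csv"),
            row.names = FALSE)
  write.csv(result$qc, file.path(out_dir, "qc_flags.csv"), row.names = FALSE)
  for (sx in names(result$strata)) {
    r <- result$strata[[sx]]
    pre <- function(name) file.path(out_dir, paste0(sx, "_", name))
    bmi_df <- data.frame(child_id = r$bmi$child_ids,
                         sex = unname(r$bmi$sex), r$bmi$values,
                         check.names = FALSE, row.names = NULL)
    names(bmi_df)[-(1:2)] <- paste0("bmi_", format(r$bmi$grid_ages,
                                                   trim = TRUE))
    write.csv(bmi_df, pre("bmi_grid.csv"), row.names = FALSE)
    write.csv(round(r$distances, 6), pre("distances.csv"))
    write.csv(data.frame(child_id = names(r$assignment$labels),
                         cluster = unname(r$assignment$labels),
                         silhouette = r$assignment$silhouette),
              pre("labels.csv"), row.names = FALSE)
    write.csv(data.frame(cluster = seq_len(r$assignment$k),
                         medoid_id = r$assignment$medoid_ids),
              pre("medoids.csv"), row.names = FALSE)
    write.csv(r$silhouette_table, pre("silhouette_by_k.csv"),
              row.names = FALSE)
    write.csv(data.frame(position = seq_along(r$heatmap_order),
                         child_id = r$bmi$child_ids[r$heatmap_order]),
              pre("heatmap_order.csv"), row.names = FALSE)
    write.csv(r$features, pre("features.csv"), row.names = FALSE)
    write.csv(r$summary, pre("feature_summary.csv"), row.names = FALSE)
    write.csv(r$peak_table, pre("peak_counts.csv"), row.names = FALSE)
  }
  manifest <- list(
    seed = result$config$seed,
    config = rapply(result$config, function(x) x, how = "replace"),
    counts = list(
      input_children = nrow(result$selection),
      kept = sum(result$selection$status == "kept"),
      strata = lapply(result$strata, function(r) length(r$bmi$child_ids))),
    package_version = as.character(utils::packageVersion("bmiphase")),
    r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
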