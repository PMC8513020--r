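#' Configuration of an end-to-end pipeline run
#'
#' Bundles every stage's parameters. The master `seed` overrides the
#' simulation seed and fans out to the partitioning and model fits, so a
#' saved configuration reproduces a run exactly.
#'
#' @param simulation A [sim_config()].
#' @param detection_filter [filter_spec()] used before heel-strike detection.
#' @param feature_filter [filter_spec()] (or `NULL`) applied to IMU channels
#'   before feature extraction.
#' @param partition A [partition_spec()].
#' @param specs List of [model_spec()]s to compare.
#' @param k_list Feature-reduction grid.
#' @param subsets Sensor-ablation subsets.
#' @param normalize Baseline-normalize features (default TRUE).
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL` to keep
#'   results in memory only.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = sim_config(),
                       detection_filter = filter_spec(6),
                       feature_filter = filter_spec(20),
                       partition = partition_spec(),
                       specs = default_model_specs(),
                       k_list = c(25, 16, 13, 11, 8),
                       subsets = c("all", "l5s1+foot", "l5s1", "foot"),
                       normalize = TRUE,
                       out_dir = NULL,
                       seed = 1L) {
  structure(list(simulation = simulation, detection_filter = detection_filter,
                 feature_filter = feature_filter, partition = partition,
                 specs = specs, k_list = k_list, subsets = subsets,
                 normalize = normalize, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full fatigue-diagnosis pipeline
#'
#' Simulate -> clean/segment -> features -> normalize -> label -> compare the
#' six classifiers -> (phase 2) feature-importance ranking, feature-reduction
#' grid and sensor ablation on the best forest. With fewer than two label
#' classes present (e.g. a single baseline bout) the modelling stages are
#' skipped with a warning.
#'
#' @param config A [run_config()].
#' @return A `fatigue_run`: list with `data` (labeled feature tibble),
#'   `windows`, `comparison`, `ranking`, `reduction`, `ablation` and a
#'   `manifest` of stage counts, seeds and (if written) file paths.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  sim$seed <- config$seed
  part <- config$partition
  part$seed <- fan_seed(config$seed, 53L)

  cohort <- simulate_cohort(sim)
  windows <- segment_cohort(cohort, filter = config$detection_filter)
  features <- extract_features(cohort, windows, filter = config$feature_filter)
  if (config$normalize) features <- normalize_features(features)
  data <- assemble_dataset(features, cohort$labels)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitfatigue")),
    seed = config$seed,
    n_participants = sim$n_participants,
    n_bouts = nrow(cohort$recordings),
    n_windows = nrow(windows),
    n_windows_kept = sum(windows$kept),
    n_rows = nrow(data),
    class_distribution = as.list(table(data$class))
  )

  comparison <- ranking <- reduction <- ablation <- NULL
  if (length(unique(data$class)) < 2) {
    warning("single fatigue class present; skipping model training",
            call. = FALSE)
  } else {
    comparison <- compare_models(data, config$specs, part)
    best <- comparison$fit[[1]]
    manifest$best_model <- comparison$algorithm[1]
    rf_fit <- if (inherits(best$model, "randomForest")) best else {
      # importance and the reduction grid are defined for the forest
      comparison$fit[[match("RF", comparison$algorithm)]]
    }
    if (!is.null(rf_fit)) {
      ranking <- rank_features(rf_fit)
      reduction <- reduce_and_eval(data, ranking, config$k_list, part)
      ablation <- sensor_ablation(data, config$subsets, part)
    }
  }

  out <- structure(list(data = data, windows = windows,
                        comparison = comparison, ranking = ranking,
                        reduction = reduction, ablation = ablation,
                        manifest = manifest, config = config),
                   class = "fatigue_run")
  if (!is.null(config$out_dir)) {
    out$manifest$files <- write_run(out, config$out_dir)
  }
  out
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  wr <- function(obj, name) {
    path <- file.path(dir, name)
    write.csv(obj, path, row.names = FALSE)
    files[[name]] <<- path
  }
  wr(run$data, "features.csv")
  wr(run$windows, "windows.csv")
  if (!is.null(run$comparison)) {
    wr(dplyr::select(run$comparison, -"fit"), "model_comparison.csv")
    wr(run$ranking, "importance.csv")
    wr(dplyr::select(run$reduction, -"fit"), "reduction_grid.csv")
    wr(dplyr::select(run$ablation, -"fit"), "sensor_ablation.csv")
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA)
  files[["manifest.json"]] <- path
  files
}

#' @export
print.fatigue_run <- function(x, ...) {
  m <- x$manifest
  cat("<fatigue_run> seed ", m$seed, ": ", m$n_rows, " labeled cycles from ",
      m$n_bouts, " bouts\n", sep = "")
  if (!is.null(x$comparison)) {
    cat("  best model: ", m$best_model, " (macro F1 ",
        sprintf("%.3f", x$comparison$f1[1]), ")\n", sep = "")
  }
  invisible(x)
}
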