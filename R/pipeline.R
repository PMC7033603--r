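#' Default pipeline configuration
#'
#' @param n_treadmill_only,n_sidewalk_only,n_both cohort sizes.
#' @param effect_scale condition contrast multiplier.
#' @param duration_s treadmill segment duration (s) / sidewalk leg length (m).
#' @param n_iterations_selection,n_iterations_classify iteration counts.
#' @param retention_threshold selection retention threshold.
#' @param alpha family-wise alpha for the feature comparisons.
#' @param k_folds cross-validation folds (capped at the training participant
#'   count).
#' @return a named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(n_treadmill_only = 28, n_sidewalk_only = 25,
                            n_both = 16, effect_scale = 1, duration_s = 300,
                            n_iterations_selection = 100,
                            n_iterations_classify = 100,
                            retention_threshold = 0.10, alpha = 0.05, k_folds = 10) {
  list(
    n_treadmill_only = n_treadmill_only, n_sidewalk_only = n_sidewalk_only,
    n_both = n_both, effect_scale = effect_scale, duration_s = duration_s,
    n_iterations_selection = n_iterations_selection,
    n_iterations_classify = n_iterations_classify,
    retention_threshold = retention_threshold, alpha = alpha, k_folds = k_folds
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), sprintf("config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  assert_that(!length(unknown),
    sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  defaults[names(config)] <- config
  defaults
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, preprocess and segment every run, extract the
#' 25-feature table, run iterated forward selection on the training rows,
#' classify with the repeated SVM experiment, and compare the retained
#' features between conditions. When `outdir` is given, writes
#' `features.csv`, `selection.json`, `selection_ranks.csv` (mean-rank
#' report), `evaluation.json`, `per_participant_counts.csv`,
#' `comparisons.csv` and `summary.txt`. The whole bundle is a deterministic
#' function of `(config, seed)`.
#'
#' @param config a list from [pipeline_config()] or a YAML file path.
#' @param seed integer master seed.
#' @param outdir optional output directory.
#' @return a `pipeline_result` list: `dataset`, `features`, `selection`,
#'   `evaluation`, `comparisons`, `descriptives`, `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1, outdir = NULL) {
  cfg <- read_pipeline_config(config)
  design <- cohort_design(
    n_treadmill_only = cfg$n_treadmill_only,
    n_sidewalk_only = cfg$n_sidewalk_only,
    n_both = cfg$n_both, effect_scale = cfg$effect_scale, seed = seed
  )
  dataset <- generate_cohort(design, duration_s = cfg$duration_s)
  features_tbl <- extract_features(dataset)
  train_tbl <- dplyr::filter(features_tbl, .data$role == "training")
  test_tbl <- dplyr::filter(features_tbl, .data$role == "testing")
  k <- min(cfg$k_folds, dplyr::n_distinct(train_tbl$participant))
  selection <- run_selection(
    train_tbl,
    n_iterations = cfg$n_iterations_selection,
    threshold = cfg$retention_threshold,
    seed = derive_seed(seed, "selection"), k = k
  )
  retained <- selection$retained
  if (!length(retained)) {
    warn("no features retained; falling back to the full feature set")
    retained <- intersect(feature_names(), names(train_tbl))
  }
  evaluation <- run_experiment(
    train_tbl, test_tbl, retained,
    n_iterations = cfg$n_iterations_classify,
    seed = derive_seed(seed, "classify"), k = k
  )
  comparisons <- compare_selected_features(train_tbl, test_tbl, retained,
    alpha = cfg$alpha)
  descriptives <- cohort_descriptives(dataset)
  result <- structure(
    list(
      dataset = dataset, features = features_tbl, selection = selection,
      evaluation = evaluation, comparisons = comparisons,
      descriptives = descriptives, config = cfg, seed = seed
    ),
    class = "pipeline_result"
  )
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$features, file.path(outdir, "features.csv"))
  sel <- result$selection
  jsonlite::write_json(
    list(
      n_iterations = sel$n_iterations, threshold = sel$threshold,
      retained = sel$retained, table = sel$table,
      per_iteration_orders = sel$per_iteration_orders
    ),
    file.path(outdir, "selection.json"),
    auto_unbox = TRUE, digits = NA
  )
  rank_report <- sel$table |>
    dplyr::filter(.data$feature %in% sel$retained) |>
    dplyr::arrange(.data$mean_rank) |>
    dplyr::select("feature", "mean_rank", "retention_frequency")
  readr::write_csv(rank_report, file.path(outdir, "selection_ranks.csv"))
  ev <- result$evaluation
  jsonlite::write_json(
    list(
      n_iterations = ev$n_iterations, features = ev$features,
      cv_accuracies = ev$cv_accuracies, test_accuracies = ev$test_accuracies,
      cv_mean = ev$cv_mean, cv_sd = ev$cv_sd,
      test_mean = ev$test_mean, test_sd = ev$test_sd
    ),
    file.path(outdir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(ev$per_participant_counts,
    file.path(outdir, "per_participant_counts.csv"))
  readr::write_csv(result$comparisons, file.path(outdir, "comparisons.csv"))
  null_band <- abs(ev$cv_mean - 50) <= 10
  lines <- c(
    sprintf("runs: %d (training rows %d, testing rows %d)",
      length(result$dataset$runs),
      sum(result$features$role == "training"),
      sum(result$features$role == "testing")),
    sprintf("effect_scale: %g", result$config$effect_scale),
    sprintf("retained features (%d): %s",
      length(sel$retained), paste(sel$retained, collapse = ", ")),
    sprintf("training participant-wise CV accuracy: %.2f%% (SD %.2f%%)",
      ev$cv_mean, ev$cv_sd),
    sprintf("independent test accuracy: %.2f%% (SD %.2f%%)",
      ev$test_mean, ev$test_sd),
    if (result$config$effect_scale == 0) {
      sprintf("null cohort: CV accuracy %s the 50%% +/- 10%% chance band",
        if (null_band) "within" else "OUTSIDE")
    },
    sprintf("significant comparisons (threshold %.4g): %d of %d",
      attr(result$comparisons, "threshold"),
      sum(result$comparisons$significant), nrow(result$comparisons))
  )
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, effect_scale %g\n", x$seed,
    x$config$effect_scale))
  print(x$selection)
  print(x$evaluation)
  invisible(x)
}
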