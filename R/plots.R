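#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_line
#'   geom_point geom_boxplot geom_jitter labs facet_wrap theme_minimal
#'   scale_y_continuous coord_flip
#' @export
ggplot2::autoplot

#' Plot a run's aligned acceleration traces
#'
#' @param sig an `aligned_signal`.
#' @param window_s time window to show, seconds (from the start of the run).
#' @return a ggplot.
#' @export
plot_aligned_signal <- function(sig, window_s = 5) {
  stopifnot(inherits(sig, "aligned_signal"))
  n <- min(nrow(sig$samples), round(window_s * sig$fs_hz))
  df <- tibble::tibble(
    time_s = (seq_len(n) - 1) / sig$fs_hz,
    VT = sig$samples[seq_len(n), "vt"],
    ML = sig$samples[seq_len(n), "ml"],
    AP = sig$samples[seq_len(n), "ap"]
  ) |>
    tidyr::pivot_longer(-"time_s", names_to = "axis", values_to = "accel")
  ggplot(df, aes(x = .data$time_s, y = .data$accel)) +
    geom_line() +
    facet_wrap(~axis, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = expression(acceleration ~ (m / s^2))) +
    theme_minimal()
}

#' @rdname autoplot_gaitenv
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = stats::reorder(.data$feature, .data$retention_frequency),
    y = .data$retention_frequency, fill = .data$retained)) +
    geom_col() +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    coord_flip() +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    labs(
      x = NULL, y = "retention frequency",
      title = sprintf("Feature retention over %d iterations", object$n_iterations)
    ) +
    theme_minimal()
}

#' Autoplot methods for pipeline results
#'
#' `autoplot.selection_result()` shows per-feature retention frequencies with
#' the retention threshold; `autoplot.eval_result()` shows the distribution
#' of per-iteration cross-validated and independent-test accuracies.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot_gaitenv
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$mode, y = .data$accuracy)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(
      x = NULL, y = "accuracy (%)",
      title = sprintf("Classification accuracy over %d iterations",
        object$n_iterations)
    ) +
    theme_minimal()
}

#' Grouped feature comparison plot
#'
#' Mean and SD of each compared feature by condition and dataset, with
#' significance flags from the Bonferroni-adjusted tests.
#'
#' @param comparisons a `comparison_table` from
#'   [compare_selected_features()].
#' @return a ggplot.
#' @export
plot_feature_comparisons <- function(comparisons) {
  stopifnot(inherits(comparisons, "comparison_table"))
  mean_cols <- grep("^mean_", names(comparisons), value = TRUE)
  conds <- sub("^mean_", "", mean_cols)
  df <- purrr::map_dfr(conds, function(cond) {
    tibble::tibble(
      feature = comparisons$feature, dataset = comparisons$dataset,
      condition = cond,
      mean = comparisons[[paste0("mean_", cond)]],
      sd = comparisons[[paste0("sd_", cond)]],
      significant = comparisons$significant
    )
  })
  ggplot(df, aes(x = .data$dataset, y = .data$mean, fill = .data$condition)) +
    geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = "feature value (mean +/- SD)") +
    theme_minimal()
}
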