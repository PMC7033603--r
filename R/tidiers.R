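#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a selection result
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return tibble with one row per candidate feature: retention frequency,
#'   selection count, mean rank and whether it was retained.
#' @export
tidy.selection_result <- function(x, ...) {
  x$table |>
    dplyr::mutate(retained = .data$feature %in% x$retained) |>
    dplyr::arrange(dplyr::desc(.data$retention_frequency), .data$mean_rank)
}

#' @rdname tidy.selection_result
#' @return for `glance`: a one-row tibble (iterations, threshold, number
#'   retained, median subset size).
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations,
    threshold = x$threshold,
    n_retained = length(x$retained),
    median_subset_size = stats::median(lengths(x$per_iteration_orders))
  )
}

#' Tidy an evaluation result
#'
#' @param x an `eval_result`.
#' @param ... unused.
#' @return tibble with one row per (iteration, evaluation mode) accuracy.
#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(
    iteration = rep(seq_len(x$n_iterations), 2),
    mode = rep(c("cv", "test"), each = x$n_iterations),
    accuracy = c(x$cv_accuracies, x$test_accuracies)
  )
}

#' @rdname tidy.eval_result
#' @return for `glance`: one row with mean/SD of both accuracy modes.
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations, n_features = length(x$features),
    cv_mean = x$cv_mean, cv_sd = x$cv_sd,
    test_mean = x$test_mean, test_sd = x$test_sd
  )
}
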