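#' Participant-wise cross-validation folds
#'
#' Partitions participants (never rows) into `k` folds, stratified by
#' condition label where group sizes allow, so no participant's rows are
#' split between training and validation.
#'
#' @param table a feature table with `participant` and `condition` columns.
#' @param k number of folds.
#' @param seed integer seed for the fold draw.
#' @return list of `k` character vectors of participant ids.
#' @export
participant_folds <- function(table, k = 10, seed = 1) {
  participants <- unique(table$participant)
  assert_that(length(participants) >= k, "k exceeds the participant count")
  # stratify: a participant's stratum is the set of conditions they ran
  strata <- table |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      stratum = paste(sort(unique(.data$condition)), collapse = "+"),
      .groups = "drop"
    )
  folds <- vector("list", k)
  with_seed(seed, {
    for (st in unique(strata$stratum)) {
      ids <- sample(strata$participant[strata$stratum == st])
      assign_to <- rep(seq_len(k), length.out = length(ids))
      # rotate the starting fold per stratum so small strata don't pile up
      assign_to <- ((assign_to + sample.int(k, 1) - 2L) %% k) + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
      }
    }
  })
  folds
}

# Two-class linear discriminant with pooled covariance and equal priors.
# Returns a prediction function. A singular pooled covariance triggers a
# ridge of 1e-8 on the diagonal with a warning.
fit_lda2 <- function(X, y) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  X0 <- X[y == classes[1], , drop = FALSE]
  X1 <- X[y == classes[2], , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  w <- tryCatch(
    solve(S, mu1 - mu0),
    error = function(e) {
      warn("singular pooled covariance in LDA; adding ridge 1e-8")
      solve(S + diag(1e-8, ncol(X)), mu1 - mu0)
    }
  )
  thresh <- sum(w * (mu0 + mu1)) / 2
  function(Xnew) {
    scores <- drop(Xnew %*% w)
    ifelse(scores > thresh, classes[2], classes[1])
  }
}

standardize_by <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Cross-validated LDA misclassification rate of a feature subset
#'
#' Fits a two-class linear discriminant (pooled covariance, equal priors) on
#' each training fold over the given feature subset, predicting the held-out
#' fold; features are standardized with training-fold statistics. The error
#' is the mean of the per-fold misclassification rates.
#'
#' @param table feature table with `participant`, `condition` and feature
#'   columns; `condition` is the class label.
#' @param subset non-empty character vector of feature names.
#' @param folds participant folds from [participant_folds()].
#' @param standardize standardize features with training-fold statistics.
#' @return mean misclassification rate in `[0, 1]`.
#' @export
lda_cv_error <- function(table, subset, folds, standardize = TRUE) {
  assert_that(length(subset) >= 1, "subset must be non-empty")
  X <- as.matrix(table[, subset, drop = FALSE])
  y <- table$condition
  errs <- vapply(folds, function(ids) {
    test <- table$participant %in% ids
    if (!any(test)) return(NA_real_)
    ytr <- y[!test]
    if (length(unique(ytr)) < 2) {
      abort("both classes must be present in every training fold",
        class = "gaitenv_degenerate_fold"
      )
    }
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (standardize) {
      ctr <- colMeans(Xtr)
      scl <- apply(Xtr, 2, sd)
      Xtr <- standardize_by(Xtr, ctr, scl)
      Xte <- standardize_by(Xte, ctr, scl)
    }
    pred <- fit_lda2(Xtr, ytr)(Xte)
    mean(pred != y[test])
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Forward-sequential feature selection
#'
#' Greedy wrapper search: at each round the candidate minimizing the
#' cross-validated LDA error of the current subset plus that candidate is
#' added; the search stops when no candidate strictly reduces the error or
#' when `max_features` is reached. Ties are broken by the lowest index in the
#' canonical feature ordering.
#'
#' @param table feature table (class label in `condition`).
#' @param folds participant folds.
#' @param features candidate features (default: all of [feature_names()]
#'   present in the table, in canonical order).
#' @param max_features cap on the subset size.
#' @return character vector of selected features in selection order, with the
#'   per-round CV errors in attribute `cv_errors`.
#' @export
forward_select <- function(table, folds, features = NULL, max_features = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_names(), names(table))
  }
  per_class <- tapply(table$participant, table$condition,
    function(p) length(unique(p)))
  assert_that(length(per_class) == 2 && all(per_class >= 2),
    "need two classes with at least 2 participants each")
  if (is.null(max_features)) max_features <- length(features)
  selected <- character(0)
  errors <- numeric(0)
  best_err <- Inf
  repeat {
    candidates <- setdiff(features, selected)
    if (!length(candidates) || length(selected) >= max_features) break
    errs <- vapply(candidates, function(f) {
      lda_cv_error(table, c(selected, f), folds)
    }, numeric(1))
    i <- which.min(errs) # which.min returns the first (lowest-index) tie
    if (errs[i] >= best_err) break
    best_err <- errs[i]
    selected <- c(selected, candidates[i])
    errors <- c(errors, best_err)
  }
  attr(selected, "cv_errors") <- errors
  selected
}

#' Aggregate per-iteration selection orders
#'
#' Computes, for every candidate feature, the fraction of iterations in which
#' it was selected (retention frequency) and its mean 1-based selection rank
#' over the iterations in which it was selected. Features with retention at
#' or above `threshold` are retained; the boundary is inclusive (a feature
#' selected in exactly 10% of iterations is kept).
#'
#' @param orders list of per-iteration selection orders (character vectors).
#' @param features the full candidate set.
#' @param threshold retention threshold (fraction of iterations).
#' @return a `selection_result`.
#' @export
aggregate_selection <- function(orders, features, threshold = 0.10) {
  n_iter <- length(orders)
  stats_tbl <- purrr::map_dfr(features, function(f) {
    ranks <- purrr::map_dbl(orders, function(o) {
      m <- match(f, o)
      if (is.na(m)) NA_real_ else m
    })
    tibble::tibble(
      feature = f,
      n_selected = sum(!is.na(ranks)),
      retention_frequency = sum(!is.na(ranks)) / n_iter,
      mean_rank = if (any(!is.na(ranks))) mean(ranks, na.rm = TRUE) else NA_real_
    )
  })
  retained <- stats_tbl |>
    dplyr::filter(.data$retention_frequency >= threshold) |>
    dplyr::arrange(.data$mean_rank)
  structure(
    list(
      per_iteration_orders = orders,
      table = stats_tbl,
      retained = retained$feature,
      threshold = threshold,
      n_iterations = n_iter
    ),
    class = "selection_result"
  )
}

#' Iterated feature selection
#'
#' Runs [forward_select()] over `n_iterations` fresh participant-wise fold
#' partitions drawn from the seeded stream, then aggregates retention
#' frequencies and mean ranks. Features selected in at least
#' `threshold * n_iterations` iterations are retained.
#'
#' @param table training feature table.
#' @param n_iterations number of iterations (default 100).
#' @param threshold retention threshold (default 0.10).
#' @param seed integer seed.
#' @param k folds per iteration.
#' @param features candidate set (default canonical).
#' @param max_features cap per iteration.
#' @return a `selection_result` with the per-iteration orders, the
#'   per-feature retention/rank table, and the retained set ordered by mean
#'   rank.
#' @export
run_selection <- function(table, n_iterations = 100, threshold = 0.10,
                          seed = 1, k = 10, features = NULL,
                          max_features = NULL) {
  if (is.null(features)) features <- intersect(feature_names(), names(table))
  orders <- vector("list", n_iterations)
  errors <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    folds <- participant_folds(table, k = k, seed = derive_seed(seed, "folds", i))
    sel <- forward_select(table, folds, features = features,
      max_features = max_features)
    orders[[i]] <- as.character(sel)
    errors[[i]] <- attr(sel, "cv_errors")
  }
  res <- aggregate_selection(orders, features, threshold)
  res$per_iteration_errors <- errors
  res$seed <- seed
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d iterations, %d/%d features retained (threshold %.0f%%)\n",
    x$n_iterations, length(x$retained), nrow(x$table), 100 * x$threshold
  ))
  if (length(x$retained)) {
    tbl <- x$table |>
      dplyr::filter(.data$feature %in% x$retained) |>
      dplyr::arrange(.data$mean_rank)
    cat(sprintf("  %-22s mean rank %.2f  retained in %3.0f%%\n",
      tbl$feature, tbl$mean_rank, 100 * tbl$retention_frequency), sep = "")
  }
  invisible(x)
}
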