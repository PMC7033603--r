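#' Train the binary SVM
#'
#' Standardizes the features with the training statistics and trains a
#' radial-basis-function support vector machine whose box constraint (cost)
#' and kernel parameter (gamma) are chosen by an inner 5-fold grid search
#' over a fixed logarithmic grid (`10^-3 .. 10^3` for both), best mean
#' accuracy winning and ties going to the smaller cost (then smaller gamma).
#' The final model is refit on all training rows with the chosen
#' hyper-parameters. The treadmill-analog condition is the positive class.
#'
#' @param train_table feature table with `participant`, `condition` and
#'   feature columns; `condition` must have exactly two levels.
#' @param features feature names to train on.
#' @param seed integer seed for the inner fold draw.
#' @param cost_grid,gamma_grid hyper-parameter grids.
#' @param inner_k inner folds for the grid search.
#' @return a `gait_svm`: the fitted [e1071::svm] model, the standardization
#'   statistics, the features and the chosen hyper-parameters.
#' @export
train_svm <- function(train_table, features, seed = 1,
                      cost_grid = 10^(-3:3), gamma_grid = 10^(-3:3),
                      inner_k = 5) {
  assert_that(all(features %in% names(train_table)),
    "missing features in training table")
  y <- factor(train_table$condition)
  if (nlevels(y) < 2) {
    abort("training data contain a single class", class = "gaitenv_single_class")
  }
  # fix the positive class: treadmill analog first when present
  lev <- levels(y)
  if ("treadmill" %in% lev) y <- factor(y, levels = c("treadmill", setdiff(lev, "treadmill")))
  X <- as.matrix(train_table[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xs <- standardize_by(X, ctr, scl)
  n <- nrow(Xs)
  fold_id <- with_seed(seed, {
    # stratified inner folds on rows
    id <- integer(n)
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      id[rows] <- rep(seq_len(inner_k), length.out = length(rows))
    }
    id
  })
  best <- list(acc = -Inf, cost = NA, gamma = NA)
  for (cost in sort(cost_grid)) {
    for (gamma in sort(gamma_grid)) {
      accs <- vapply(seq_len(inner_k), function(f) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
        fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
          kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
        )
        mean(predict(fit, Xs[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
      acc <- mean(accs, na.rm = TRUE)
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, cost = cost, gamma = gamma)
      }
    }
  }
  model <- e1071::svm(Xs, y,
    kernel = "radial", cost = best$cost, gamma = best$gamma, scale = FALSE
  )
  structure(
    list(
      model = model, center = ctr, scale = scl, features = features,
      cost = best$cost, gamma = best$gamma, inner_cv_accuracy = best$acc,
      levels = levels(y)
    ),
    class = "gait_svm"
  )
}

#' Predict with a trained gait SVM
#'
#' @param object a `gait_svm`.
#' @param newdata feature table containing the model's features.
#' @param ... unused.
#' @return factor of predicted conditions.
#' @export
predict.gait_svm <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata))) {
    abort("newdata is missing model features", class = "gaitenv_missing_features")
  }
  X <- standardize_by(
    as.matrix(newdata[, object$features, drop = FALSE]),
    object$center, object$scale
  )
  predict(object$model, X)
}

#' Participant-wise k-fold cross-validated accuracy
#'
#' Partitions participants (not rows) into `k` folds; for each fold an SVM is
#' trained on the remaining participants and the held-out rows are predicted.
#' Accuracy is correct predictions over all rows, as a percentage.
#'
#' @param train_table training feature table.
#' @param features features to use.
#' @param k folds.
#' @param seed integer seed (fold partition and inner SVM searches).
#' @param ... passed to [train_svm()].
#' @return accuracy in percent, with per-row predictions in attribute
#'   `predictions`.
#' @export
participantwise_kfold_accuracy <- function(train_table, features, k = 10,
                                           seed = 1, ...) {
  folds <- participant_folds(train_table, k = k, seed = derive_seed(seed, "cvfolds"))
  preds <- rep(NA_character_, nrow(train_table))
  for (f in seq_along(folds)) {
    held <- train_table$participant %in% folds[[f]]
    if (!any(held)) next
    fit <- train_svm(train_table[!held, , drop = FALSE], features,
      seed = derive_seed(seed, "svm", f), ...)
    preds[held] <- as.character(predict(fit, train_table[held, , drop = FALSE]))
  }
  acc <- 100 * mean(preds == train_table$condition)
  attr(acc, "predictions") <- tibble::tibble(
    participant = train_table$participant,
    condition = train_table$condition,
    predicted = preds,
    fold = vapply(train_table$participant, function(p) {
      which(vapply(folds, function(ids) p %in% ids, logical(1)))[1]
    }, integer(1))
  )
  acc
}

#' Evaluate a model on the independent testing cohort
#'
#' Each testing participant contributes one prediction per condition;
#' accuracy is over all rows.
#'
#' @param model a `gait_svm`.
#' @param test_table testing feature table.
#' @return a list: `accuracy` (percent) and `predictions` tibble
#'   (participant, condition, predicted, correct).
#' @export
evaluate_independent <- function(model, test_table) {
  pred <- as.character(predict(model, test_table))
  predictions <- tibble::tibble(
    participant = test_table$participant,
    condition = test_table$condition,
    predicted = pred,
    correct = pred == test_table$condition
  )
  list(accuracy = 100 * mean(predictions$correct), predictions = predictions)
}

#' Repeated classification experiment
#'
#' Per iteration: a fresh participant-wise 10-fold cross-validation of the
#' training table, and an SVM trained on all training rows evaluated on the
#' independent testing table. Accuracies and per-participant per-condition
#' correct-prediction counts are aggregated over iterations.
#'
#' @param train_table,test_table feature tables.
#' @param features retained features to classify on (non-empty).
#' @param n_iterations repetitions (default 100).
#' @param seed integer master seed.
#' @param k cross-validation folds.
#' @param ... passed to [train_svm()].
#' @return an `eval_result`: per-iteration CV and test accuracies (percent),
#'   their mean/SD, the per-participant count table (max = `n_iterations`),
#'   and the per-iteration fold assignments (for leakage audits).
#' @export
run_experiment <- function(train_table, test_table, features,
                           n_iterations = 100, seed = 1, k = 10, ...) {
  assert_that(length(features) >= 1, "retained feature set is empty")
  cv_acc <- numeric(n_iterations)
  test_acc <- numeric(n_iterations)
  counts <- NULL
  fold_assignments <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    acc_i <- participantwise_kfold_accuracy(
      train_table, features, k = k, seed = derive_seed(seed, "iter", i), ...
    )
    fold_assignments[[i]] <- attr(acc_i, "predictions") |>
      dplyr::mutate(iteration = i)
    cv_acc[i] <- as.numeric(acc_i)
    fit <- train_svm(train_table, features,
      seed = derive_seed(seed, "final", i), ...)
    ev <- evaluate_independent(fit, test_table)
    test_acc[i] <- ev$accuracy
    inc <- ev$predictions |>
      dplyr::mutate(correct = as.integer(.data$correct)) |>
      dplyr::select("participant", "condition", "correct")
    counts <- if (is.null(counts)) inc else {
      dplyr::left_join(counts, inc, by = c("participant", "condition")) |>
        dplyr::mutate(correct = .data$correct.x + .data$correct.y) |>
        dplyr::select("participant", "condition", "correct")
    }
  }
  per_participant <- counts |>
    tidyr::pivot_wider(names_from = "condition", values_from = "correct")
  structure(
    list(
      cv_accuracies = cv_acc, test_accuracies = test_acc,
      cv_mean = mean(cv_acc), cv_sd = sd(cv_acc),
      test_mean = mean(test_acc), test_sd = sd(test_acc),
      per_participant_counts = per_participant,
      fold_assignments = dplyr::bind_rows(fold_assignments),
      n_iterations = n_iterations, features = features, seed = seed
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<eval_result> %d iterations on %d features\n",
      "  training 10-fold CV accuracy: %.2f%% (SD %.2f%%)\n",
      "  independent test accuracy:    %.2f%% (SD %.2f%%)\n"
    ),
    x$n_iterations, length(x$features),
    x$cv_mean, x$cv_sd, x$test_mean, x$test_sd
  ))
  invisible(x)
}
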