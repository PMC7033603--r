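#' Canonical feature names
#'
#' The 25 features describing one run: mean speed, step/stride timing CVs,
#' resultant RMS, and per axis (AP, ML, VT) the step and stride regularity,
#' symmetry (step/stride regularity ratio), mean per-step peak, RMS, across-
#' step RMS CV, and RMS ratio. The order is the canonical ordering used for
#' deterministic tie-breaks in feature selection.
#'
#' @return character vector of length 25.
#' @export
feature_names <- function() {
  axes <- c("ap", "ml", "vt")
  c(
    "speed", "step_time_cv", "stride_time_cv", "rms_resultant",
    paste0("regularity_step_", axes), paste0("regularity_stride_", axes),
    paste0("symmetry_", axes), paste0("peak_", axes), paste0("rms_", axes),
    paste0("rms_cv_", axes), paste0("ratio_", axes)
  )
}

#' Unbiased autocorrelation coefficient at a single lag
#'
#' `[sum(x_t * x_(t+lag)) / (n - lag)] / [sum(x_t^2) / n]`: the lag-`lag`
#' autocovariance with the unbiased `n - lag` normalization, divided by the
#' biased variance. At lag 0 this is exactly 1; on noiseless periodic signals
#' at the period lag it is 1 up to edge effects (and may marginally exceed 1,
#' since the numerator averages over fewer terms than the denominator).
#'
#' @param x numeric vector; must not have zero variance. The mean is removed
#'   internally.
#' @param lag non-negative integer lag in samples, below `length(x) / 2`.
#' @return the coefficient.
#' @export
unbiased_autocorr <- function(x, lag) {
  n <- length(x)
  lag <- as.integer(lag)
  assert_that(lag >= 0 && lag < n / 2, "lag must lie in [0, n/2)")
  x <- x - mean(x)
  denom <- sum(x^2) / n
  if (denom == 0) {
    abort("zero-variance input", class = "gaitenv_zero_variance")
  }
  if (lag == 0) return(1)
  num <- sum(x[1:(n - lag)] * x[(lag + 1):n]) / (n - lag)
  num / denom
}

#' Step/stride regularity and symmetry for one axis
#'
#' Regularity is the unbiased autocorrelation of the (mean-removed) axis
#' signal at the mean step lag and mean stride lag; higher values indicate a
#' more consistent gait pattern. Symmetry is the ratio of step to stride
#' regularity: 1 indicates a left/right-symmetric gait.
#'
#' @param x single-axis signal.
#' @param step_lag,stride_lag lags in samples (rounded mean step and stride
#'   durations).
#' @return named list `regularity_step`, `regularity_stride`, `symmetry`
#'   (`NA` when stride regularity is 0).
#' @export
regularity_and_symmetry <- function(x, step_lag, stride_lag) {
  r_step <- unbiased_autocorr(x, step_lag)
  r_stride <- unbiased_autocorr(x, stride_lag)
  symmetry <- if (r_stride == 0) NA_real_ else r_step / r_stride
  list(
    regularity_step = r_step, regularity_stride = r_stride,
    symmetry = symmetry
  )
}

#' Temporal coefficient of variation
#'
#' Sample SD (n-1 denominator) over mean: the step-time and stride-time CV.
#'
#' @param durations numeric vector of at least 2 durations, seconds.
#' @return dimensionless CV.
#' @export
temporal_cv <- function(durations) {
  assert_that(length(durations) >= 2, "need at least 2 durations")
  m <- mean(durations)
  if (m == 0) abort("zero mean duration", class = "gaitenv_zero_mean")
  sd(durations) / m
}

# length-weighted mean of the per-segment unbiased autocorrelation: segments
# are separate recordings, and correlating across their junction would bias
# regularity downward for multi-segment runs
segmentwise_autocorr <- function(x, segments, lag) {
  vals <- vapply(segments, function(seg) {
    unbiased_autocorr(x[seg_rows(seg)], lag)
  }, numeric(1))
  w <- vapply(segments, function(seg) seg[2] - seg[1], numeric(1))
  sum(vals * w) / sum(w)
}

# mean-removed (per segment, per axis) continuous signal of an aligned run
centered_signal <- function(sig) {
  x <- sig$samples
  for (seg in sig$segments) {
    rows <- seg_rows(seg)
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, colMeans(x[rows, , drop = FALSE]))
  }
  x
}

#' Magnitude features
#'
#' Per axis: peak (mean over retained steps of the per-step maximum absolute
#' acceleration), RMS of the whole mean-removed signal, across-step CV of the
#' per-step RMS, and the RMS ratio (axis RMS over resultant RMS). The
#' resultant RMS is the RMS of the per-sample Euclidean norm of the three
#' mean-removed axes, so the squared ratios sum to exactly 1.
#'
#' @param seg a `step_segmentation` (per-step statistics come from its
#'   50-point step matrix).
#' @param sig the `aligned_signal` the segmentation was built from.
#' @return named list of the 14 magnitude features.
#' @export
magnitude_features <- function(seg, sig) {
  stopifnot(inherits(seg, "step_segmentation"), inherits(sig, "aligned_signal"))
  assert_that(dim(seg$step_matrix)[1] >= 2, "need at least 2 retained steps")
  x <- centered_signal(sig)
  rms <- function(v) sqrt(mean(v^2))
  rms_resultant <- rms(sqrt(rowSums(x^2)))
  if (rms_resultant == 0) {
    abort("zero resultant RMS", class = "gaitenv_zero_variance")
  }
  out <- list(rms_resultant = rms_resultant)
  for (ax in c("ap", "ml", "vt")) {
    steps <- seg$step_matrix[, , ax]
    step_means <- rowMeans(steps)
    centered_steps <- steps - step_means
    per_step_rms <- sqrt(rowMeans(centered_steps^2))
    out[[paste0("peak_", ax)]] <- mean(apply(abs(steps), 1, max))
    out[[paste0("rms_", ax)]] <- rms(x[, ax])
    out[[paste0("rms_cv_", ax)]] <- sd(per_step_rms) / mean(per_step_rms)
    out[[paste0("ratio_", ax)]] <- rms(x[, ax]) / rms_resultant
  }
  out
}

#' Extract the 25-feature vector of one run
#'
#' Runs preprocessing (when given a `raw_run`), step segmentation, and the
#' temporal, regularity and magnitude feature computations, and assembles the
#' named 25-feature vector. Regularity/RMS quantities are computed on the
#' continuous mean-removed aligned signal at the unnormalized time base
#' (regularity per segment, length-weighted, since segments are separate
#' recordings); per-step peak and RMS statistics come from the 50-point step
#' matrix. Regularities are clipped to `[-1, 1]` (the unbiased estimator can
#' marginally exceed 1 on perfectly periodic signals).
#'
#' @param run a `raw_run` or an already-preprocessed `aligned_signal`.
#' @param n_points points per normalized step.
#' @param ... passed to [preprocess_run()] when `run` is raw.
#' @return a named numeric vector of length 25, with attributes
#'   `participant`, `condition` and `n_steps`.
#' @export
extract_feature_vector <- function(run, n_points = 50, ...) {
  sig <- if (inherits(run, "aligned_signal")) run else preprocess_run(run, ...)
  seg <- segment_steps(sig, n_points = n_points)
  step_lag <- max(1L, round(mean(seg$step_durations_s) * sig$fs_hz))
  stride_lag <- max(1L, round(mean(seg$stride_durations_s) * sig$fs_hz))
  x <- centered_signal(sig)
  feats <- list(
    speed = sig$speed_mps,
    step_time_cv = temporal_cv(seg$step_durations_s),
    stride_time_cv = temporal_cv(seg$stride_durations_s)
  )
  for (ax in c("ap", "ml", "vt")) {
    r_step <- segmentwise_autocorr(x[, ax], sig$segments, step_lag)
    r_stride <- segmentwise_autocorr(x[, ax], sig$segments, stride_lag)
    feats[[paste0("regularity_step_", ax)]] <- min(1, max(-1, r_step))
    feats[[paste0("regularity_stride_", ax)]] <- min(1, max(-1, r_stride))
    feats[[paste0("symmetry_", ax)]] <-
      if (r_stride == 0) NA_real_ else r_step / r_stride
  }
  feats <- c(feats, magnitude_features(seg, sig))
  out <- unlist(feats)[feature_names()]
  attr(out, "participant") <- sig$participant
  attr(out, "condition") <- sig$condition
  attr(out, "n_steps") <- dim(seg$step_matrix)[1]
  out
}

#' Extract the feature table of a cohort
#'
#' Applies [extract_feature_vector()] to every run of a dataset and binds the
#' results into the interchange feature table: one row per (participant,
#' condition) with role and the 25 feature columns.
#'
#' @param dataset a `gait_dataset` from [generate_cohort()] or
#'   [load_dataset()].
#' @param ... passed to [extract_feature_vector()].
#' @return a tibble with columns `participant`, `condition`, `role`, and the
#'   25 features.
#' @export
extract_features <- function(dataset, ...) {
  stopifnot(inherits(dataset, "gait_dataset"))
  rows <- purrr::map(dataset$runs, function(run) {
    fv <- extract_feature_vector(run, ...)
    role <- dataset$manifest$role[
      dataset$manifest$participant == run$participant &
        dataset$manifest$condition == run$condition
    ]
    dplyr::bind_cols(
      tibble::tibble(
        participant = run$participant, condition = run$condition,
        role = role[1]
      ),
      tibble::as_tibble_row(as.list(fv))
    )
  })
  dplyr::bind_rows(rows)
}
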