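#' Low-pass filter a raw run
#'
#' Applies a 4th-order low-pass Butterworth filter (default cutoff 10 Hz)
#' to each axis of each segment independently. The filter is applied
#' zero-phase (forward-backward, [signal::filtfilt()]), which avoids timing
#' bias in step detection at the cost of doubling the stop-band attenuation.
#'
#' @param run a `raw_run`.
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order.
#' @return the filtered `raw_run`.
#' @export
butterworth_lowpass <- function(run, cutoff_hz = 10, order = 4) {
  stopifnot(inherits(run, "raw_run"))
  if (cutoff_hz >= run$fs_hz / 2) {
    abort("cutoff_hz must be below the Nyquist frequency",
      class = "gaitenv_bad_cutoff"
    )
  }
  bf <- signal::butter(order, cutoff_hz / (run$fs_hz / 2), type = "low")
  out <- run$samples
  for (seg in run$segments) {
    rows <- seg_rows(seg)
    for (j in 1:3) {
      out[rows, j] <- zero_phase_filter(run$samples[rows, j], bf, run$fs_hz)
    }
  }
  run$samples <- out
  run
}

# Forward-backward filtering with mean removal and odd-reflection padding, so
# edges carry no start-up transient (signal::filtfilt assumes zero initial
# conditions).
zero_phase_filter <- function(x, bf, fs_hz) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, as.integer(ceiling(1.5 * fs_hz)))
  left <- 2 * xc[1] - xc[(pad + 1):2]
  right <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(left, xc, right))
  y[(pad + 1):(pad + n)] + mu
}

#' Trim segment edges
#'
#' Removes the first and last `fraction` of each segment independently
#' (default 5%), discarding start/stop transients. Exactly
#' `floor(fraction * length)` samples are dropped from each end of each
#' segment; segment bookkeeping is rebuilt on the shortened signal.
#'
#' @param run a `raw_run`.
#' @param fraction fraction in `[0, 0.5)` removed from each end.
#' @return the trimmed `raw_run`.
#' @export
trim_segments <- function(run, fraction = 0.05) {
  stopifnot(inherits(run, "raw_run"))
  assert_that(fraction >= 0 && fraction < 0.5, "fraction must lie in [0, 0.5)")
  kept <- list()
  new_segments <- list()
  offset <- 0L
  for (seg in run$segments) {
    len <- seg[2] - seg[1]
    cut <- floor(fraction * len)
    lo <- seg[1] + cut
    hi <- seg[2] - cut
    if ((hi - lo) < 2 * run$fs_hz) {
      abort("trimmed segment shorter than 2 s", class = "gaitenv_too_short")
    }
    kept[[length(kept) + 1]] <- run$samples[(lo + 1L):hi, , drop = FALSE]
    new_segments[[length(new_segments) + 1]] <- c(offset, offset + (hi - lo))
    offset <- offset + (hi - lo)
  }
  old_segments <- run$segments
  run$samples <- do.call(rbind, kept)
  run$segments <- new_segments
  if (!is.null(run$truth) && !is.null(run$truth$contacts)) {
    # map planted contact indices into the trimmed index space
    mapped <- integer(0)
    for (i in seq_along(old_segments)) {
      seg <- old_segments[[i]]
      cut <- floor(fraction * (seg[2] - seg[1]))
      lo <- seg[1] + cut # 0-based first kept sample
      hi <- seg[2] - cut # 0-based past-the-end
      inside <- run$truth$contacts[run$truth$contacts > lo &
        run$truth$contacts <= hi]
      mapped <- c(mapped, as.integer(inside - lo + new_segments[[i]][1]))
    }
    run$truth$contacts <- mapped
  }
  run
}

#' Align the vertical axis with gravity
#'
#' Estimates the gravity direction as the mean acceleration direction over
#' the run (a quasi-static assumption: the dynamic components of steady-state
#' running average out over whole steps) and applies the minimal rotation
#' taking it onto the true vertical. The per-segment VT mean — gravity plus
#' the mean dynamic lift — is then subtracted, so the returned VT signal has
#' zero mean per segment. Horizontal axes remain provisional until
#' [align_heading()].
#'
#' @param run a filtered, trimmed `raw_run`.
#' @return an `aligned_signal`: samples in (VT, ML, AP) order, m/s^2, with
#'   the applied rotation, the estimated tilt angle (degrees) and run
#'   metadata carried through.
#' @export
align_gravity <- function(run) {
  stopifnot(inherits(run, "raw_run"))
  # sensor (ax right, ay up, az posterior) -> device anatomical (ML, AP, VT)
  dev <- cbind(
    ml = run$samples[, 1], ap = -run$samples[, 3], vt = run$samples[, 2]
  )
  g_dev <- colMeans(dev)
  g_mag <- sqrt(sum(g_dev^2))
  if (g_mag < 5) {
    abort("mean acceleration magnitude below 5 m/s^2: gravity not captured",
      class = "gaitenv_no_gravity"
    )
  }
  R1 <- rotation_between(g_dev, c(0, 0, 1))
  rotated <- dev %*% t(R1)
  vt <- rotated[, 3]
  for (seg in run$segments) {
    rows <- seg_rows(seg)
    vt[rows] <- vt[rows] - mean(vt[rows])
  }
  structure(
    list(
      samples = cbind(vt = vt, ml = rotated[, 1], ap = rotated[, 2]),
      fs_hz = run$fs_hz, segments = run$segments,
      rotation_applied = R1,
      tilt_deg_estimate = angle_between_deg(g_dev, c(0, 0, 1)),
      heading_deg_estimate = NA_real_,
      heading_degenerate = FALSE,
      participant = run$participant, condition = run$condition,
      speed_mps = run$speed_mps, truth = run$truth
    ),
    class = "aligned_signal"
  )
}

#' Align the horizontal axes with the direction of motion
#'
#' Rotates the horizontal plane so that the anterior-posterior axis carries
#' the dominant horizontal acceleration variance (principal axis of the
#' centered ML/AP covariance). The forward sign is chosen so that the mean
#' signed AP skewness is non-negative, a deterministic tie-break; the ML sign
#' follows to keep the frame right-handed. A purely biphasic AP pattern has
#' zero skewness, so on such signals the forward sign is unidentifiable and
#' resolved by the (arbitrary) sign of the numerical skewness.
#'
#' @param sig an `aligned_signal` from [align_gravity()].
#' @return the `aligned_signal` with AP/ML fixed, the composed rotation in
#'   `rotation_applied` and the estimated heading (degrees) recorded. If the
#'   horizontal variance is isotropic to within 1e-12 the rotation is the
#'   identity and `heading_degenerate` is set with a warning.
#' @export
align_heading <- function(sig) {
  stopifnot(inherits(sig, "aligned_signal"))
  ml <- sig$samples[, "ml"] - mean(sig$samples[, "ml"])
  ap <- sig$samples[, "ap"] - mean(sig$samples[, "ap"])
  C <- stats::cov(cbind(ml, ap))
  if (abs(C[1, 1] - C[2, 2]) < 1e-12 && abs(C[1, 2]) < 1e-12) {
    warn("horizontal variance is isotropic; heading left unchanged")
    sig$heading_deg_estimate <- 0
    sig$heading_degenerate <- TRUE
    return(sig)
  }
  ev <- eigen(C, symmetric = TRUE)
  u <- ev$vectors[, 1] # (ml, ap) components of the dominant horizontal axis
  # project AP onto the dominant axis, ML onto its right-handed orthogonal
  R2 <- rbind(
    c(u[2], -u[1], 0),
    c(u[1], u[2], 0),
    c(0, 0, 1)
  ) # acts on (ML, AP, VT) column vectors
  hor <- cbind(
    sig$samples[, "ml"] * u[2] - sig$samples[, "ap"] * u[1],
    sig$samples[, "ml"] * u[1] + sig$samples[, "ap"] * u[2]
  )
  if (skewness(hor[, 2]) < 0) {
    hor <- -hor
    R2[1:2, ] <- -R2[1:2, ]
    u <- -u
  }
  sig$samples <- cbind(vt = sig$samples[, "vt"], ml = hor[, 1], ap = hor[, 2])
  sig$rotation_applied <- R2 %*% sig$rotation_applied
  # report in the convention of the planted misalignment (rotation of the AP
  # axis within the horizontal plane), normalized to (-90, 90]
  est <- -atan2(u[1], u[2]) * 180 / pi
  est <- ((est + 90) %% 180) - 90
  sig$heading_deg_estimate <- if (est == -90) 90 else est
  sig
}

#' Full preprocessing pipeline
#'
#' Filter, trim, gravity-align and heading-align one raw run, in that order.
#'
#' @param run a `raw_run`.
#' @inheritParams butterworth_lowpass
#' @inheritParams trim_segments
#' @return an `aligned_signal`.
#' @export
preprocess_run <- function(run, cutoff_hz = 10, order = 4, fraction = 0.05) {
  run |>
    butterworth_lowpass(cutoff_hz = cutoff_hz, order = order) |>
    trim_segments(fraction = fraction) |>
    align_gravity() |>
    align_heading()
}

#' @export
print.aligned_signal <- function(x, ...) {
  cat(sprintf(
    "<aligned_signal> %s/%s: %d samples @ %.2f Hz, %d segment(s), tilt %.2f deg\n",
    x$participant, x$condition, nrow(x$samples), x$fs_hz,
    length(x$segments), x$tilt_deg_estimate
  ))
  invisible(x)
}
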