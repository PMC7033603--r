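#' Dominant step period of a vertical acceleration signal
#'
#' Scans the unbiased autocorrelation of the mean-removed VT signal over the
#' physiological step-period band (0.25-1.0 s) and returns the lag of the
#' first dominant peak: the smallest-lag local maximum whose coefficient is at
#' least half the band maximum. Taking the first such peak (rather than the
#' global maximum) avoids locking onto the stride lag when left/right
#' asymmetry makes the stride peak marginally higher.
#'
#' @param vt numeric vector, vertical acceleration (any constant offset is
#'   removed internally).
#' @param fs_hz sampling rate, Hz.
#' @param band physiological search band in seconds.
#' @return the dominant step period, seconds.
#' @export
dominant_step_period <- function(vt, fs_hz, band = c(0.25, 1.0)) {
  assert_that(length(vt) >= 10 * fs_hz, "need at least 10 s of signal")
  x <- vt - mean(vt)
  lags <- seq.int(max(1L, floor(band[1] * fs_hz) - 1L), ceiling(band[2] * fs_hz) + 1L)
  ac <- vapply(lags, function(l) unbiased_autocorr(x, l), numeric(1))
  k <- seq(2, length(ac) - 1)
  is_peak <- ac[k] > ac[k - 1] & ac[k] >= ac[k + 1]
  in_band <- lags[k] >= band[1] * fs_hz & lags[k] <= band[2] * fs_hz
  peaks <- k[is_peak & in_band]
  peaks <- peaks[ac[peaks] > 0.1]
  if (!length(peaks)) {
    abort("no autocorrelation peak in the step-period band: signal not gait-like",
      class = "gaitenv_not_gait"
    )
  }
  dominant <- peaks[ac[peaks] >= 0.5 * max(ac[peaks])]
  lags[dominant[1]] / fs_hz
}

#' Detect initial contacts
#'
#' Picks local maxima of the VT acceleration that exceed its 60th percentile,
#' enforcing a minimum spacing of half the dominant step period, then refines
#' each candidate to the VT minimum in the interval since the previous peak
#' (the inter-pulse valley, which marks the contact itself rather than the
#' mid-stance peak roughly half a step later). Applied per segment; detected
#' indices are global (1-based) into the run's samples.
#'
#' @param vt numeric vector, vertical acceleration of the whole run.
#' @param fs_hz sampling rate, Hz.
#' @param period_s dominant step period from [dominant_step_period()].
#' @param segments list of 0-based half-open segment intervals; default one
#'   segment covering the signal.
#' @return integer vector of contact sample indices, strictly increasing.
#' @export
detect_initial_contacts <- function(vt, fs_hz, period_s,
                                    segments = list(c(0L, length(vt)))) {
  min_gap <- max(1L, ceiling(0.5 * period_s * fs_hz))
  contacts <- integer(0)
  for (seg in segments) {
    x <- vt[seg_rows(seg)]
    thr <- quantile(x, 0.60, names = FALSE)
    pk <- pracma::findpeaks(x, minpeakheight = thr, minpeakdistance = min_gap)
    if (is.null(pk)) next
    peaks <- sort(pk[, 2])
    seg_contacts <- integer(length(peaks))
    for (j in seq_along(peaks)) {
      lo <- if (j == 1) max(1L, peaks[1] - round(period_s * fs_hz)) else peaks[j - 1]
      window <- lo:peaks[j]
      seg_contacts[j] <- window[which.min(x[window])]
    }
    # valley refinement can only shrink gaps; re-impose the minimum spacing
    keep <- c(TRUE, diff(seg_contacts) >= min_gap)
    seg_contacts <- seg_contacts[keep]
    contacts <- c(contacts, seg_contacts + seg[1])
  }
  if (length(contacts) < 30) {
    abort("fewer than 30 contacts detected: insufficient strides",
      class = "gaitenv_too_few_steps"
    )
  }
  sort(unique(contacts))
}

#' Build the 50-point time-normalized step matrix
#'
#' Segments the aligned signal at the detected contacts, discards steps whose
#' duration falls outside `[0.5, 2.5] x` half the dominant period, i.e.
#' `[0.25, 1.25] x` the period itself — a guard that in particular excludes
#' the double-length interval left by a missed contact — and linearly
#' resamples each retained step to
#' `n_points` points per axis. Stride durations are sums of two consecutive
#' retained steps (same foot to same foot).
#'
#' @param sig an `aligned_signal`.
#' @param contacts contact indices from [detect_initial_contacts()].
#' @param n_points points per normalized step (default 50).
#' @param period_s dominant step period, seconds; estimated from the VT axis
#'   when omitted.
#' @param drop_edge_steps exclude the first and last step of every segment
#'   (default `TRUE`): contact placement at trimmed segment edges is
#'   unreliable (a partial pulse survives the trim), and keeping edge steps
#'   biases timing-variability estimates of multi-segment runs.
#' @return a `step_segmentation`: contacts, step and stride durations
#'   (seconds), the `n_steps x n_points x 3` step matrix (axes VT, ML, AP),
#'   the dominant period and the number of excluded steps.
#' @export
build_step_matrix <- function(sig, contacts, n_points = 50, period_s = NULL,
                              drop_edge_steps = TRUE) {
  stopifnot(inherits(sig, "aligned_signal"))
  assert_that(length(contacts) >= 2, "need at least 2 contacts")
  if (is.null(period_s)) {
    period_s <- dominant_step_period(sig$samples[, "vt"], sig$fs_hz)
  }
  seg_of <- function(idx) {
    for (i in seq_along(sig$segments)) {
      if (idx > sig$segments[[i]][1] && idx <= sig$segments[[i]][2]) return(i)
    }
    NA_integer_
  }
  starts <- contacts[-length(contacts)]
  ends <- contacts[-1]
  step_seg <- vapply(seq_along(starts), function(i) {
    s1 <- seg_of(starts[i]); s2 <- seg_of(ends[i])
    if (!is.na(s1) && !is.na(s2) && s1 == s2) s1 else NA_integer_
  }, integer(1))
  same_seg <- !is.na(step_seg)
  durations <- (ends - starts) / sig$fs_hz
  in_band <- durations >= 0.25 * period_s & durations <= 1.25 * period_s
  keep <- same_seg & in_band
  if (drop_edge_steps) {
    for (s in unique(step_seg[!is.na(step_seg)])) {
      idx <- which(step_seg == s)
      keep[c(idx[1], idx[length(idx)])] <- FALSE
    }
  }
  n_steps <- sum(keep)
  assert_that(n_steps >= 2, "fewer than 2 retained steps")
  mat <- array(NA_real_, dim = c(n_steps, n_points, 3),
    dimnames = list(NULL, NULL, c("vt", "ml", "ap")))
  u <- seq(0, 1, length.out = n_points)
  ki <- which(keep)
  for (r in seq_along(ki)) {
    i <- ki[r]
    rows <- starts[i]:ends[i]
    xin <- seq(0, 1, length.out = length(rows))
    for (ax in c("vt", "ml", "ap")) {
      mat[r, , ax] <- approx(xin, sig$samples[rows, ax], xout = u)$y
    }
  }
  # strides pair two consecutive retained steps that are adjacent in time
  adjacent <- ki[-1] == ki[-length(ki)] + 1
  stride_durations <- durations[ki[-length(ki)][adjacent]] +
    durations[ki[-1][adjacent]]
  structure(
    list(
      contacts = contacts, step_durations_s = durations[keep],
      stride_durations_s = stride_durations,
      step_matrix = mat, dominant_period_s = period_s,
      n_excluded = sum(!keep), fs_hz = sig$fs_hz
    ),
    class = "step_segmentation"
  )
}

#' Segment an aligned run into steps
#'
#' Convenience wrapper: dominant period, contact detection and step-matrix
#' construction in one call.
#'
#' @param sig an `aligned_signal`.
#' @param n_points points per normalized step.
#' @return a `step_segmentation`.
#' @export
segment_steps <- function(sig, n_points = 50) {
  stopifnot(inherits(sig, "aligned_signal"))
  period_s <- dominant_step_period(sig$samples[, "vt"], sig$fs_hz)
  contacts <- detect_initial_contacts(
    sig$samples[, "vt"], sig$fs_hz, period_s, sig$segments
  )
  build_step_matrix(sig, contacts, n_points = n_points, period_s = period_s)
}

#' @export
print.step_segmentation <- function(x, ...) {
  cat(sprintf(
    "<step_segmentation> %d steps (%d excluded), period %.3f s, mean step %.3f s\n",
    dim(x$step_matrix)[1], x$n_excluded, x$dominant_period_s,
    mean(x$step_durations_s)
  ))
  invisible(x)
}

#' Export a step matrix as a tibble
#'
#' One row per retained step with 150 value columns (50 normalized points for
#' each of VT, ML, AP), suitable for CSV export and inspection.
#'
#' @param seg a `step_segmentation`.
#' @return a tibble.
#' @export
step_matrix_tbl <- function(seg) {
  stopifnot(inherits(seg, "step_segmentation"))
  n <- dim(seg$step_matrix)[1]
  np <- dim(seg$step_matrix)[2]
  out <- lapply(c("vt", "ml", "ap"), function(ax) {
    m <- seg$step_matrix[, , ax, drop = FALSE]
    dim(m) <- c(n, np)
    colnames(m) <- sprintf("%s_%02d", ax, seq_len(np))
    tibble::as_tibble(m)
  })
  dplyr::bind_cols(tibble::tibble(step = seq_len(n)), out)
}
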