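# Shared fixtures, all built in code.

# A short noiseless run config: deterministic signal structure, integer
# samples-per-step when fs * period is integer.
quiet_cfg <- function(..., duration_s = 40) {
  defaults <- list(
    timing_jitter_sd = 0, amp_jitter_sd = 0, lr_asymmetry = 0,
    noise_sd = 0, tilt_deg = c(0, 0), heading_deg = 0,
    duration_s = duration_s
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# Wrap a plain samples matrix as a raw_run (one segment).
matrix_run <- function(samples, fs_hz = 201.03, condition = "consistent",
                       participant = "PX", speed_mps = 2.8) {
  structure(
    list(
      samples = samples, fs_hz = fs_hz,
      segments = list(c(0L, nrow(samples))),
      condition = condition, participant = participant,
      speed_mps = speed_mps, truth = NULL
    ),
    class = "raw_run"
  )
}

# Feature table with one informative feature among noise features.
# Participants are unique per row (single-condition design).
planted_table <- function(n_per_class = 26, n_noise = 24, delta = 2.5,
                          seed = 1, informative = "feat_01") {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    noise <- matrix(rnorm(n * n_noise), n, n_noise)
    colnames(noise) <- sprintf("noise_%02d", seq_len(n_noise))
    cond <- rep(c("treadmill", "sidewalk"), each = n_per_class)
    tbl <- tibble::as_tibble(noise)
    tbl[[informative]] <- rnorm(n) + ifelse(cond == "treadmill", delta, 0)
    dplyr::bind_cols(
      tibble::tibble(
        participant = sprintf("P%03d", seq_len(n)),
        condition = cond, role = "training"
      ),
      tbl
    )
  })
}

# O(n^2) brute-force oracle for the unbiased autocorrelation coefficient.
brute_autocorr <- function(x, lag) {
  n <- length(x)
  x <- x - mean(x)
  num <- 0
  for (t in seq_len(n - lag)) num <- num + x[t] * x[t + lag]
  (num / (n - lag)) / (sum(x^2) / n)
}

# Smallest angular distance between two axis orientations (mod 180 degrees).
axis_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, max(-1, sum(a * b)))) * 180 / pi
}

is_orthonormal <- function(R, tol = 1e-9) {
  max(abs(crossprod(R) - diag(3))) < tol
}
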