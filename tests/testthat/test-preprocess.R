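test_that("low-pass filter: unit DC gain, strong 50 Hz attenuation, near-unity 1 Hz gain", {
  fs <- 201.03
  n <- 4000
  t <- (seq_len(n) - 1) / fs
  const <- matrix_run(cbind(rep(2, n), rep(9.81, n), rep(-1, n)), fs_hz = fs)
  out <- butterworth_lowpass(const)
  expect_lt(max(abs(out$samples - const$samples)), 1e-9)

  mid <- seq(round(n / 4), round(3 * n / 4)) # avoid edge transients
  hi <- matrix_run(matrix(sin(2 * pi * 50 * t), n, 3), fs_hz = fs)
  hi_amp <- max(abs(butterworth_lowpass(hi)$samples[mid, 1]))
  expect_lt(hi_amp, 0.01)

  lo <- matrix_run(matrix(sin(2 * pi * 1 * t), n, 3), fs_hz = fs)
  lo_amp <- max(abs(butterworth_lowpass(lo)$samples[mid, 1]))
  expect_gt(lo_amp, 0.99)

  expect_error(butterworth_lowpass(const, cutoff_hz = 101), class = "gaitenv_bad_cutoff")
})

test_that("filter is idempotent on band-limited signals", {
  run <- generate_run(quiet_cfg(noise_sd = 0.3), seed = 8)
  once <- butterworth_lowpass(run)
  twice <- butterworth_lowpass(once)
  rel <- sqrt(mean((twice$samples - once$samples)^2)) / sqrt(mean(once$samples^2))
  expect_lt(rel, 0.01)
})

test_that("trimming removes floor(fraction * length) per end of each segment independently", {
  fs <- 201.03
  x <- matrix(rnorm(3000), 1000, 3)
  one <- matrix_run(x, fs_hz = fs)
  tr <- trim_segments(one, 0.05)
  expect_equal(nrow(tr$samples), 900)
  expect_identical(tr$samples, x[51:950, ])
  expect_equal(tr$segments, list(c(0, 900)))

  two <- matrix_run(rbind(x, x), fs_hz = fs)
  two$segments <- list(c(0L, 1000L), c(1000L, 2000L))
  tr2 <- trim_segments(two, 0.05)
  expect_equal(nrow(tr2$samples), 1800)
  expect_identical(tr2$samples[1:900, ], x[51:950, ])
  expect_identical(tr2$samples[901:1800, ], x[51:950, ])
  expect_equal(tr2$segments, list(c(0, 900), c(900, 1800)))

  expect_identical(trim_segments(one, 0)$samples, one$samples)
  short <- matrix_run(matrix(rnorm(1200), 400, 3), fs_hz = fs)
  expect_error(trim_segments(short, 0.05), class = "gaitenv_too_short")
  expect_error(trim_segments(one, 0.5), class = "gaitenv_error")
})

test_that("gravity alignment recovers planted tilt within 0.5 degrees and zeroes the VT mean", {
  for (tilt in list(c(10, 5), c(15, 0), c(0, 14), c(-12, 8))) {
    cfg <- make_archetype("consistent", 1,
      duration_s = 40, noise_sd = 0,
      tilt_deg = tilt, heading_deg = 0
    )
    run <- generate_run(cfg, seed = 21)
    sig <- run |>
      butterworth_lowpass() |>
      trim_segments(0.05) |>
      align_gravity()
    true_tilt <- angle_between_deg(run$truth$rotation[, 3], c(0, 0, 1))
    expect_lt(abs(sig$tilt_deg_estimate - true_tilt), 0.5)
    for (seg in sig$segments) {
      rows <- (seg[1] + 1):seg[2]
      expect_lt(abs(mean(sig$samples[rows, "vt"])), 0.05)
    }
    expect_true(is_orthonormal(sig$rotation_applied, 1e-9))
  }
})

test_that("gravity alignment of an already-vertical signal is the identity, and gravity-free input is rejected", {
  fs <- 200
  t <- (0:7999) / fs
  vt_only <- matrix_run(cbind(0, 9.81 + sin(2 * pi * 3 * t), 0), fs_hz = fs)
  sig <- align_gravity(vt_only)
  expect_lt(max(abs(sig$rotation_applied - diag(3))), 1e-6)

  weightless <- matrix_run(cbind(0, rep(0.5, 1000), 0), fs_hz = fs)
  expect_error(align_gravity(weightless), class = "gaitenv_no_gravity")
})

test_that("heading alignment recovers planted headings within 1 degree (mod 180)", {
  for (h in c(0, 15, 30, 44, -40)) {
    cfg <- make_archetype("variable", 1,
      duration_s = 40, noise_sd = 0,
      tilt_deg = c(0, 0), heading_deg = h
    )
    sig <- preprocess_run(generate_run(cfg, seed = 31))
    expect_lt(axis_angle_diff(sig$heading_deg_estimate, h), 1)
  }
})

test_that("heading alignment warns and keeps the identity on isotropic horizontal variance", {
  fs <- 200
  t <- (0:3999) / fs
  circ <- matrix_run(cbind(cos(2 * pi * 2 * t), 9.81, -sin(2 * pi * 2 * t)), fs_hz = fs)
  g <- align_gravity(circ)
  expect_warning(out <- align_heading(g), "isotropic")
  expect_true(out$heading_degenerate)
  expect_identical(out$samples, g$samples)
})

test_that("rotations preserve the per-sample resultant magnitude", {
  run <- generate_run(
    make_archetype("consistent", 1,
      duration_s = 40, tilt_deg = c(8, -4), heading_deg = 25
    ),
    seed = 41
  )
  pre <- align_gravity(trim_segments(butterworth_lowpass(run), 0.05))
  post <- align_heading(pre)
  m_pre <- sqrt(pre$samples[, "ml"]^2 + pre$samples[, "ap"]^2)
  m_post <- sqrt(post$samples[, "ml"]^2 + post$samples[, "ap"]^2)
  expect_lt(max(abs(m_pre - m_post)), 1e-9)
})

test_that("full preprocessing recovers the planted anatomical signal to within 2% RMS (noise-free)", {
  cfg <- make_archetype("consistent", 1,
    duration_s = 40, noise_sd = 0,
    tilt_deg = c(10, 5), heading_deg = 30
  )
  run <- generate_run(cfg, seed = 11, keep_truth_signal = TRUE)
  sig <- preprocess_run(run)
  truth_run <- run
  truth_run$samples <- cbind(
    ax = run$truth$anat[, "ml"], ay = run$truth$anat[, "vt"],
    az = -run$truth$anat[, "ap"]
  )
  tsig <- trim_segments(butterworth_lowpass(truth_run), 0.05)
  truth_mat <- cbind(
    vt = tsig$samples[, 2], ml = tsig$samples[, 1], ap = -tsig$samples[, 3]
  )
  truth_mat <- sweep(truth_mat, 2, colMeans(truth_mat))
  got <- sweep(sig$samples, 2, colMeans(sig$samples))
  rms <- function(m) sqrt(mean(m^2))
  direct <- rms(got - truth_mat) / rms(truth_mat)
  flipped <- got
  flipped[, c("ml", "ap")] <- -flipped[, c("ml", "ap")]
  flip <- rms(flipped - truth_mat) / rms(truth_mat)
  # the biphasic AP pulse has zero skew, so the forward sign is unidentifiable
  expect_lt(min(direct, flip), 0.02)
})
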