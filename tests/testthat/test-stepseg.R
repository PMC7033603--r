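test_that("dominant step period matches the planted period and a pure sinusoid's period", {
  fs <- 201.03
  run <- generate_run(quiet_cfg(step_period_s = 0.35), seed = 3)
  sig <- preprocess_run(run)
  est <- dominant_step_period(sig$samples[, "vt"], fs)
  expect_lt(abs(est - 0.35), 1 / fs)

  t <- (0:4999) / fs
  est_sin <- dominant_step_period(sin(2 * pi * 3 * t), fs)
  expect_lt(abs(est_sin - 1 / 3), 1 / fs)

  expect_error(dominant_step_period(rnorm(3000), fs), class = "gaitenv_not_gait")
  expect_error(dominant_step_period(sin(2 * pi * 3 * t[1:1000]), fs), class = "gaitenv_error")
})

test_that("the period estimate is robust to additive noise", {
  cfg0 <- quiet_cfg(step_period_s = 0.35)
  cfgn <- quiet_cfg(step_period_s = 0.35, noise_sd = 0.5)
  p0 <- dominant_step_period(
    preprocess_run(generate_run(cfg0, seed = 12))$samples[, "vt"], 201.03
  )
  pn <- dominant_step_period(
    preprocess_run(generate_run(cfgn, seed = 12))$samples[, "vt"], 201.03
  )
  expect_lt(abs(p0 - pn), 2 / 201.03)
})

test_that("detected contacts match planted onsets within 2 samples with equal count", {
  run <- generate_run(quiet_cfg(), seed = 17)
  sig <- run |>
    butterworth_lowpass() |>
    trim_segments(0) |>
    align_gravity() |>
    align_heading()
  period <- dominant_step_period(sig$samples[, "vt"], run$fs_hz)
  det <- detect_initial_contacts(sig$samples[, "vt"], run$fs_hz, period, sig$segments)
  planted <- run$truth$contacts
  expect_equal(length(det), length(planted))
  offsets <- vapply(det, function(d) min(abs(planted - d)), numeric(1))
  expect_lte(max(offsets), 2)
  # enforced spacing
  expect_true(all(diff(det) >= 0.5 * period * run$fs_hz))
})

test_that("a missing pulse produces an out-of-band interval that the outlier rule excludes", {
  run <- generate_run(quiet_cfg(), seed = 23)
  sig <- run |>
    butterworth_lowpass() |>
    trim_segments(0) |>
    align_gravity() |>
    align_heading()
  # knock out one mid-run pulse
  k <- 40
  a <- run$truth$contacts[k]
  b <- run$truth$contacts[k + 1]
  sig$samples[a:b, "vt"] <- 0
  period <- dominant_step_period(sig$samples[, "vt"], run$fs_hz)
  contacts <- detect_initial_contacts(sig$samples[, "vt"], run$fs_hz, period, sig$segments)
  seg <- build_step_matrix(sig, contacts, period_s = period)
  expect_gte(seg$n_excluded, 1)
  expect_true(all(seg$step_durations_s <= 1.25 * period))
  expect_true(all(seg$step_durations_s >= 0.25 * period))
})

test_that("noiseless step counts match the planted counts in at least 95% of seeds", {
  hits <- vapply(1:20, function(s) {
    run <- generate_run(quiet_cfg(duration_s = 30 * 0.35 + 5), seed = 100 + s)
    sig <- run |>
      butterworth_lowpass() |>
      trim_segments(0) |>
      align_gravity() |>
      align_heading()
    period <- dominant_step_period(sig$samples[, "vt"], run$fs_hz)
    det <- detect_initial_contacts(sig$samples[, "vt"], run$fs_hz, period, sig$segments)
    length(det) == length(run$truth$contacts)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("every normalized step has exactly 50 points, endpoints and lines preserved", {
  run <- generate_run(quiet_cfg(timing_jitter_sd = 0.03, noise_sd = 0.2), seed = 29)
  sig <- preprocess_run(run)
  seg <- segment_steps(sig)
  expect_equal(dim(seg$step_matrix)[2], 50)
  expect_false(anyNA(seg$step_matrix))

  # linear ramp within one step stays on the line after resampling
  fs <- 200
  t <- (0:7999) / fs
  vt <- sin(2 * pi * 3 * t)
  lin <- structure(
    list(
      samples = cbind(vt = vt, ml = 2 * t, ap = 1 - 3 * t),
      fs_hz = fs, segments = list(c(0L, 8000L)),
      participant = "PX", condition = "x", speed_mps = 3,
      rotation_applied = diag(3), tilt_deg_estimate = 0,
      heading_deg_estimate = 0, heading_degenerate = FALSE, truth = NULL
    ),
    class = "aligned_signal"
  )
  contacts <- seq(1L, 7801L, by = 65L) # steps of 65 samples at period ~1/3 s
  out <- build_step_matrix(lin, contacts, period_s = 65 / fs, drop_edge_steps = FALSE)
  # endpoints: first and last normalized points equal the raw contact samples
  expect_equal(out$step_matrix[1, 1, "ml"], lin$samples[contacts[1], "ml"])
  expect_equal(out$step_matrix[1, 50, "ml"], lin$samples[contacts[2], "ml"])
  # interior: the ML ramp is linear in time, so the 50 points are collinear
  diffs <- apply(out$step_matrix[, , "ml"], 1, function(row) max(abs(diff(diff(row)))))
  expect_lt(max(diffs), 1e-9)

  # a step already 50 samples long keeps its endpoints exactly
  contacts50 <- c(1L, 50L, 99L)
  out50 <- build_step_matrix(lin, contacts50, period_s = 49 / fs, drop_edge_steps = FALSE)
  expect_identical(out50$step_matrix[1, 1, "ap"], lin$samples[1, "ap"])
  expect_identical(out50$step_matrix[1, 50, "ap"], lin$samples[50, "ap"])
})

test_that("stride durations are sums of their component steps and fit the segment", {
  run <- generate_run(quiet_cfg(timing_jitter_sd = 0.04), seed = 31)
  sig <- preprocess_run(run)
  seg <- segment_steps(sig)
  # with no exclusions, strides pair consecutive steps
  if (seg$n_excluded == 2) { # only the two edge steps dropped
    d <- seg$step_durations_s
    expect_equal(seg$stride_durations_s, d[-length(d)] + d[-1], tolerance = 1e-9)
  }
  total_s <- nrow(sig$samples) / sig$fs_hz
  expect_lte(sum(seg$step_durations_s), total_s)
})
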