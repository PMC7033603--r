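test_that("unbiased autocorrelation matches its definition and the brute-force oracle", {
  expect_identical(unbiased_autocorr(rnorm(100), 0), 1)

  # noiseless periodic signal at the period lag
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 4 * t) # period 50 samples
  expect_equal(unbiased_autocorr(x, 50), 1, tolerance = 1e-6)

  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(100:300, 1)
      x <- rnorm(n)
      lag <- sample(0:(floor(n / 2) - 1), 1)
      expect_equal(unbiased_autocorr(x, lag), brute_autocorr(x, lag),
        tolerance = 1e-10
      )
    }
  })

  expect_error(unbiased_autocorr(rep(3, 100), 10), class = "gaitenv_zero_variance")
  expect_error(unbiased_autocorr(rnorm(100), 60), class = "gaitenv_error")
})

test_that("regularity is invariant to amplitude scaling", {
  withr::with_seed(5, x <- sin(seq(0, 40 * pi, length.out = 2000)) + rnorm(2000, 0, 0.2))
  r1 <- regularity_and_symmetry(x, 50, 100)
  r2 <- regularity_and_symmetry(1000 * x, 50, 100)
  expect_equal(r1$regularity_step, r2$regularity_step, tolerance = 1e-9)
  expect_equal(r1$regularity_stride, r2$regularity_stride, tolerance = 1e-9)
  expect_equal(r1$symmetry, r2$symmetry, tolerance = 1e-9)
})

test_that("symmetric noiseless gait has VT and AP symmetry near 1", {
  run <- generate_run(quiet_cfg(), seed = 9)
  fv <- extract_feature_vector(run, fraction = 0.02)
  expect_lt(abs(fv["symmetry_vt"] - 1), 0.02)
  expect_lt(abs(fv["symmetry_ap"] - 1), 0.02)
})

test_that("planted left/right asymmetry depresses VT step regularity below stride regularity", {
  diffs <- vapply(1:20, function(s) {
    run <- generate_run(quiet_cfg(lr_asymmetry = 0.2, noise_sd = 0.1), seed = 300 + s)
    fv <- extract_feature_vector(run, fraction = 0.02)
    fv["regularity_stride_vt"] - fv["regularity_step_vt"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("timing jitter lowers both VT regularities", {
  reg <- function(jit) {
    rowMeans(vapply(1:20, function(s) {
      run <- generate_run(quiet_cfg(timing_jitter_sd = jit, noise_sd = 0.1), seed = 400 + s)
      fv <- extract_feature_vector(run, fraction = 0.02)
      c(fv["regularity_step_vt"], fv["regularity_stride_vt"])
    }, numeric(2)))
  }
  r0 <- reg(0)
  r5 <- reg(0.05)
  expect_lt(r5[1], r0[1])
  expect_lt(r5[2], r0[2])
})

test_that("temporal CV matches hand computation, is zero for constants and scale-invariant", {
  expect_equal(temporal_cv(c(0.3, 0.4)), 0.0707107 / 0.35, tolerance = 1e-5)
  expect_equal(temporal_cv(c(0.3, 0.4)), 0.20203, tolerance = 1e-5)
  expect_identical(temporal_cv(rep(0.35, 10)), 0)
  d <- c(0.31, 0.35, 0.33, 0.36)
  expect_equal(temporal_cv(2 * d), temporal_cv(d), tolerance = 1e-12)
  expect_error(temporal_cv(0.3), class = "gaitenv_error")
  expect_error(temporal_cv(c(0, 0)), class = "gaitenv_zero_mean")
})

test_that("a VT-only signal has ratio_vt 1 and zero horizontal ratios", {
  run <- generate_run(quiet_cfg(amp_ml = 0, amp_ap = 0), seed = 13)
  suppressWarnings(sig <- preprocess_run(run, fraction = 0.02))
  seg <- segment_steps(sig)
  mf <- magnitude_features(seg, sig)
  expect_equal(mf$ratio_vt, 1, tolerance = 1e-9)
  expect_equal(mf$ratio_ml, 0, tolerance = 1e-9)
  expect_equal(mf$ratio_ap, 0, tolerance = 1e-9)
})

test_that("squared RMS ratios sum to one on every cohort run", {
  ds <- generate_cohort(
    cohort_design(n_treadmill_only = 4, n_sidewalk_only = 4, n_both = 2, seed = 3),
    duration_s = 60
  )
  ft <- extract_features(ds)
  ss <- ft$ratio_ap^2 + ft$ratio_ml^2 + ft$ratio_vt^2
  expect_true(all(abs(ss - 1) < 1e-9))
})

test_that("amplitude jitter raises the VT RMS CV", {
  cv <- function(jit) {
    mean(vapply(1:20, function(s) {
      run <- generate_run(quiet_cfg(amp_jitter_sd = jit, noise_sd = 0.1), seed = 500 + s)
      unname(extract_feature_vector(run, fraction = 0.02)["rms_cv_vt"])
    }, numeric(1)))
  }
  expect_gt(cv(0.08), cv(0.02))
})

test_that("feature extraction yields exactly the 25 named features, deterministically", {
  run <- generate_run(make_archetype("variable", 1, duration_s = 40), seed = 19)
  fv1 <- extract_feature_vector(run)
  fv2 <- extract_feature_vector(run)
  expect_identical(names(fv1), feature_names())
  expect_length(fv1, 25)
  expect_identical(fv1, fv2)
  expect_true(all(fv1[grep("^regularity", names(fv1))] >= -1))
  expect_true(all(fv1[grep("^regularity", names(fv1))] <= 1))
  expect_true(all(fv1[grep("cv", names(fv1))] >= 0))
})

test_that("archetype cohorts reproduce the planted energy-share contrast", {
  feat <- function(arch) {
    t(vapply(1:20, function(s) {
      run <- generate_run(make_archetype(arch, 1, duration_s = 40), seed = 600 + s)
      fv <- extract_feature_vector(run)
      fv[c("ratio_vt", "ratio_ap")]
    }, numeric(2)))
  }
  cons <- feat("consistent")
  vari <- feat("variable")
  expect_gt(mean(cons[, 1]), mean(vari[, 1])) # ratio_vt: consistent higher
  expect_gt(mean(vari[, 2]), mean(cons[, 2])) # ratio_ap: variable higher
})
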