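#' Synthetic run configuration
#'
#' Builds and validates the parameter set for one synthetic participant-run.
#' The signal model is a quasi-periodic pulse train: alternating left/right
#' steps of duration `T_i = step_period_s * (1 + eta_i)` with
#' `eta_i ~ N(0, timing_jitter_sd^2)`; within each step the vertical (VT)
#' acceleration is a half-sine pulse, the anterior-posterior (AP) acceleration
#' a biphasic full-sine pulse, and the medio-lateral (ML) acceleration a
#' half-sine whose sign alternates with the stance foot. Per-step amplitude
#' multipliers are `(1 + eps_i) * (1 + lr_asymmetry)` for right steps and
#' `(1 + eps_i) * (1 - lr_asymmetry)` for left steps, with
#' `eps_i ~ N(0, amp_jitter_sd^2)`. Gravity (9.81 m/s^2) is added along the
#' true vertical, the whole signal is rotated into the sensor frame by the
#' tilt and heading misalignments, and white noise is added.
#'
#' @param step_period_s nominal step period T0 in seconds.
#' @param timing_jitter_sd SD of the per-step duration multiplier (must be
#'   in `[0, 0.2)`).
#' @param amp_vt,amp_ml,amp_ap pulse amplitudes, m/s^2.
#' @param amp_jitter_sd SD of the per-step amplitude multiplier.
#' @param lr_asymmetry right/left amplitude asymmetry `gamma` in `[0, 1)`.
#' @param tilt_deg length-2 numeric `(roll, pitch)` sensor misalignment in
#'   degrees (roll about the AP axis, pitch about the ML axis).
#' @param heading_deg rotation of the AP axis within the horizontal plane,
#'   degrees.
#' @param noise_sd additive white-noise SD, m/s^2.
#' @param duration_s duration of each segment, seconds (must allow at least
#'   30 steps).
#' @param fs_hz sampling rate, Hz.
#' @param speed_mps mean running speed carried as run metadata.
#' @param n_segments 1 (treadmill analog) or 2 (sidewalk analog, two
#'   independently generated out-and-back legs).
#' @param slow_mod_amp relative amplitude of a slow (`slow_mod_hz`) sinusoidal
#'   modulation of all pulse amplitudes, emulating overground
#'   non-stationarity (inclines, curves). 0 disables it.
#' @param slow_mod_hz frequency of the slow modulation, Hz.
#'
#' @return a `synth_config` list.
#' @export
synth_config <- function(step_period_s = 0.35,
                         timing_jitter_sd = 0.03,
                         amp_vt = 10,
                         amp_ml = 2,
                         amp_ap = 3.5,
                         amp_jitter_sd = 0.06,
                         lr_asymmetry = 0.05,
                         tilt_deg = c(0, 0),
                         heading_deg = 0,
                         noise_sd = 0.4,
                         duration_s = 300,
                         fs_hz = 201.03,
                         speed_mps = 2.78,
                         n_segments = 1,
                         slow_mod_amp = 0,
                         slow_mod_hz = 0.05) {
  cfg <- list(
    step_period_s = step_period_s, timing_jitter_sd = timing_jitter_sd,
    amp_vt = amp_vt, amp_ml = amp_ml, amp_ap = amp_ap,
    amp_jitter_sd = amp_jitter_sd, lr_asymmetry = lr_asymmetry,
    tilt_deg = tilt_deg, heading_deg = heading_deg, noise_sd = noise_sd,
    duration_s = duration_s, fs_hz = fs_hz, speed_mps = speed_mps,
    n_segments = as.integer(n_segments),
    slow_mod_amp = slow_mod_amp, slow_mod_hz = slow_mod_hz
  )
  assert_that(step_period_s > 0, "step_period_s must be positive")
  assert_that(fs_hz > 0, "fs_hz must be positive")
  assert_that(timing_jitter_sd >= 0 && timing_jitter_sd < 0.2,
    "timing_jitter_sd must lie in [0, 0.2)")
  assert_that(lr_asymmetry >= 0 && lr_asymmetry < 1,
    "lr_asymmetry must lie in [0, 1)")
  assert_that(amp_jitter_sd >= 0, "amp_jitter_sd must be non-negative")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(length(tilt_deg) == 2, "tilt_deg must be (roll, pitch)")
  assert_that(cfg$n_segments %in% c(1L, 2L), "n_segments must be 1 or 2")
  assert_that(duration_s >= 30 * step_period_s,
    "duration_s too short: fewer than 30 steps per segment")
  structure(cfg, class = "synth_config")
}

#' Archetype configurations for the two running regimes
#'
#' Returns the generator configuration encoding a "consistent"
#' (treadmill-like) or "variable" (overground-like) gait regime. The two
#' archetypes differ only in timing jitter, amplitude jitter and the VT/AP
#' amplitude shares; all differences vanish at `effect_scale = 0`, so a
#' null cohort is exchangeable between conditions. The consistent archetype
#' has lower stride-to-stride timing and amplitude variability and a larger
#' vertical energy share; the variable archetype has larger variability and a
#' larger anterior-posterior share.
#'
#' @param condition `"consistent"` or `"variable"`.
#' @param effect_scale non-negative multiplier on the archetype differences;
#'   1 gives the default contrast, 0 removes it.
#' @param ... further arguments forwarded to [synth_config()] (e.g.
#'   `duration_s` for small test runs).
#'
#' @return a `synth_config`.
#' @export
make_archetype <- function(condition = c("consistent", "variable"),
                           effect_scale = 1, ...) {
  if (length(condition) != 1 || !condition %in% c("consistent", "variable")) {
    abort(
      sprintf("unknown condition label: %s", paste(condition, collapse = "/")),
      class = "gaitenv_bad_condition"
    )
  }
  assert_that(effect_scale >= 0, "effect_scale must be non-negative")
  e <- effect_scale
  sgn <- if (condition == "consistent") -1 else 1
  synth_config(
    timing_jitter_sd = 0.03 + sgn * 0.015 * e,
    amp_jitter_sd = 0.06 + sgn * 0.03 * e,
    amp_vt = 10 * (1 - sgn * 0.10 * e),
    amp_ap = 3.5 * (1 + sgn * 0.15 * e),
    ...
  )
}

# Simulate the step sequence of one segment: onsets, durations, feet and
# per-step amplitude multipliers. Only complete steps are emitted; the tail
# of the segment past the last complete step carries no dynamic signal.
simulate_steps <- function(cfg) {
  t_end <- cfg$duration_s
  n_guess <- ceiling(t_end / cfg$step_period_s * 1.5) + 10
  durations <- cfg$step_period_s * (1 + rnorm(n_guess, 0, cfg$timing_jitter_sd))
  durations <- pmax(durations, 0.2 * cfg$step_period_s)
  onsets <- c(0, cumsum(durations))[seq_len(n_guess)]
  keep <- which(onsets + durations <= t_end)
  n_steps <- length(keep)
  if (n_steps < 30) {
    abort("segment duration too short for at least 30 complete steps",
      class = "gaitenv_too_short"
    )
  }
  feet <- rep(c("L", "R"), length.out = n_steps)
  eps <- rnorm(n_steps, 0, cfg$amp_jitter_sd)
  m <- (1 + eps) * ifelse(feet == "R", 1 + cfg$lr_asymmetry, 1 - cfg$lr_asymmetry)
  list(
    onsets = onsets[keep], durations = durations[keep],
    feet = feet, m = m, n_steps = n_steps
  )
}

# Dense dynamic signal of one segment in anatomical axes (ML, AP, VT).
segment_dynamics <- function(cfg, steps, t) {
  n <- length(t)
  ml <- numeric(n); ap <- numeric(n); vt <- numeric(n)
  ends <- steps$onsets + steps$durations
  idx <- findInterval(t, steps$onsets)
  in_step <- idx >= 1 & t < ends[pmax(idx, 1)]
  k <- idx[in_step]
  u <- (t[in_step] - steps$onsets[k]) / steps$durations[k]
  s <- ifelse(steps$feet[k] == "R", 1, -1)
  vt[in_step] <- cfg$amp_vt * steps$m[k] * sin(pi * u)
  ap[in_step] <- cfg$amp_ap * steps$m[k] * sin(2 * pi * u)
  ml[in_step] <- s * cfg$amp_ml * steps$m[k] * sin(pi * u)
  if (cfg$slow_mod_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    mod <- 1 + cfg$slow_mod_amp * sin(2 * pi * cfg$slow_mod_hz * t + phase)
    vt <- vt * mod; ap <- ap * mod; ml <- ml * mod
  }
  cbind(ml = ml, ap = ap, vt = vt)
}

#' Generate one synthetic participant-run
#'
#' Simulates the sensor-frame tri-axial acceleration of a single run under
#' the signal model described in [synth_config()], together with the planted
#' truth (contact sample indices, stance feet, applied rotation and,
#' optionally, the noise-free anatomical-frame signal) that downstream tests
#' validate against.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the whole run is a deterministic function of
#'   `(config, participant_effects, seed)`.
#' @param participant_effects optional named list of multipliers
#'   (`period`, `amp_vt`, `amp_ml`, `amp_ap`) shared across a participant's
#'   runs.
#' @param participant,condition metadata labels carried through the pipeline.
#' @param keep_truth_signal if `TRUE`, the noise-free anatomical-frame signal
#'   is stored in the planted truth (memory-heavy; used by alignment tests).
#'
#' @return a `raw_run`: sensor-frame samples (`ax` right, `ay` vertical,
#'   `az` posterior; m/s^2), sampling rate, 0-based half-open segment
#'   intervals, labels, speed, and a `truth` list.
#' @export
generate_run <- function(config, seed, participant_effects = NULL,
                         participant = "P01", condition = "consistent",
                         keep_truth_signal = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  pe <- list(
    period = 1, amp_vt = 1, amp_ml = 1, amp_ap = 1,
    jitter_timing = 1, jitter_amp = 1
  )
  if (!is.null(participant_effects)) pe[names(participant_effects)] <- participant_effects
  cfg <- config
  cfg$step_period_s <- cfg$step_period_s * pe$period
  cfg$amp_vt <- cfg$amp_vt * pe$amp_vt
  cfg$amp_ml <- cfg$amp_ml * pe$amp_ml
  cfg$amp_ap <- cfg$amp_ap * pe$amp_ap
  cfg$timing_jitter_sd <- min(cfg$timing_jitter_sd * pe$jitter_timing, 0.19)
  cfg$amp_jitter_sd <- cfg$amp_jitter_sd * pe$jitter_amp
  assert_that(cfg$duration_s >= 30 * cfg$step_period_s,
    "duration_s too short: fewer than 30 steps per segment")

  n_seg <- round(cfg$duration_s * cfg$fs_hz)
  # device orientation: heading about vertical, then roll about AP and pitch
  # about ML; device reading d = R %*% a for anatomical (ML, AP, VT) vector a
  R <- rot_about_ml(deg2rad(cfg$tilt_deg[2])) %*%
    rot_about_ap(deg2rad(cfg$tilt_deg[1])) %*%
    rot_about_vt(deg2rad(cfg$heading_deg))

  with_seed(seed, {
    seg_list <- vector("list", cfg$n_segments)
    truth_contacts <- integer(0)
    truth_feet <- character(0)
    truth_anat <- if (keep_truth_signal) vector("list", cfg$n_segments) else NULL
    segments <- vector("list", cfg$n_segments)
    offset <- 0L
    for (s in seq_len(cfg$n_segments)) {
      steps <- simulate_steps(cfg)
      t <- (seq_len(n_seg) - 1) / cfg$fs_hz
      anat <- segment_dynamics(cfg, steps, t)
      if (keep_truth_signal) truth_anat[[s]] <- anat
      a <- anat
      a[, "vt"] <- a[, "vt"] + 9.81
      d <- a %*% t(R) # rows are samples; device components (ml', ap', vt')
      sensor <- cbind(ax = d[, 1], ay = d[, 3], az = -d[, 2])
      if (cfg$noise_sd > 0) {
        sensor <- sensor + matrix(rnorm(3 * n_seg, 0, cfg$noise_sd), n_seg, 3)
      }
      seg_list[[s]] <- sensor
      truth_contacts <- c(truth_contacts, offset + round(steps$onsets * cfg$fs_hz) + 1L)
      truth_feet <- c(truth_feet, steps$feet)
      segments[[s]] <- c(offset, offset + n_seg)
      offset <- offset + n_seg
    }
    samples <- do.call(rbind, seg_list)
    structure(
      list(
        samples = samples, fs_hz = cfg$fs_hz, segments = segments,
        condition = condition, participant = participant,
        speed_mps = cfg$speed_mps,
        truth = list(
          contacts = truth_contacts, feet = truth_feet,
          rotation = R, config = cfg,
          anat = if (keep_truth_signal) do.call(rbind, truth_anat) else NULL
        )
      ),
      class = "raw_run"
    )
  })
}

#' Cohort design
#'
#' Mirrors a three-protocol study: one group runs only in the consistent
#' (treadmill-like) environment, one only in the variable (sidewalk-like)
#' environment, and an independent group runs in both. The first two groups
#' form the training data, the both-conditions group the testing data.
#'
#' @param n_treadmill_only,n_sidewalk_only,n_both group sizes (defaults
#'   28, 25, 16).
#' @param effect_scale multiplier on all condition differences (archetype
#'   contrasts, speed contrast, overground amplitude modulation); 0 yields an
#'   exchangeable null cohort.
#' @param seed integer master seed.
#' @param test_effect_attenuation fraction in `[0, 1)` by which the testing
#'   participants' condition contrast is attenuated; nonzero values emulate a
#'   testing cohort whose runners differ from the training population
#'   (an overfitting probe).
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_treadmill_only = 28, n_sidewalk_only = 25,
                          n_both = 16, effect_scale = 1, seed = 1,
                          test_effect_attenuation = 0) {
  assert_that(n_treadmill_only >= 0 && n_sidewalk_only >= 0 && n_both >= 0,
    "group sizes must be non-negative")
  assert_that(n_both >= 2, "n_both must be at least 2 for paired testing")
  assert_that(effect_scale >= 0, "effect_scale must be non-negative")
  assert_that(test_effect_attenuation >= 0 && test_effect_attenuation < 1,
    "test_effect_attenuation must lie in [0, 1)")
  structure(
    list(
      n_treadmill_only = as.integer(n_treadmill_only),
      n_sidewalk_only = as.integer(n_sidewalk_only),
      n_both = as.integer(n_both),
      effect_scale = effect_scale, seed = as.integer(seed),
      test_effect_attenuation = test_effect_attenuation
    ),
    class = "cohort_design"
  )
}

# Condition-level structure applied on top of the archetypes. The speed
# contrast and the overground slow amplitude modulation scale with
# effect_scale so that the null cohort stays exchangeable.
condition_speed <- function(condition, effect_scale) {
  if (condition == "treadmill") {
    c(mean = 2.78, sd = 0.26)
  } else {
    c(mean = 2.78 + 0.46 * effect_scale, sd = 0.26 + 0.16 * effect_scale)
  }
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant random effects once (log-normal multipliers on step
#' period, axis amplitudes and speed, SD 0.05 on the log scale) and shares
#' them across that participant's runs, then generates every run from an RNG
#' stream derived from `(seed, participant, condition)` so that adding
#' participants never perturbs existing ones. Treadmill-analog runs are one
#' 300 s segment; sidewalk-analog runs are two independently generated legs
#' of 300 m each (duration 300 m / speed), with a slow amplitude modulation
#' whose depth scales with `effect_scale`.
#'
#' @param design a [cohort_design()].
#' @param duration_s treadmill-analog segment duration in seconds and,
#'   numerically, the sidewalk-analog leg length in meters (default 300:
#'   a 5-minute treadmill run and two 300 m sidewalk legs lasting
#'   `300 / speed` seconds each). Scaling it down shrinks both protocols
#'   proportionally for small test cohorts.
#' @param keep_truth_signal stored per run when `TRUE` (memory-heavy).
#' @return a `gait_dataset`: list of `raw_run`s plus a manifest tibble
#'   (participant, protocol, condition, role, speed, demographics).
#' @export
generate_cohort <- function(design, duration_s = 300, keep_truth_signal = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  ids <- c(
    sprintf("T%02d", seq_len(design$n_treadmill_only)),
    sprintf("S%02d", seq_len(design$n_sidewalk_only)),
    sprintf("B%02d", seq_len(design$n_both))
  )
  protocol <- rep(c(1L, 2L, 3L),
    c(design$n_treadmill_only, design$n_sidewalk_only, design$n_both))
  runs <- list()
  manifest <- list()
  for (i in seq_along(ids)) {
    pid <- ids[i]
    proto <- protocol[i]
    pseed <- derive_seed(design$seed, pid)
    pe <- with_seed(pseed, list(
      period = exp(rnorm(1, 0, 0.05)),
      amp_vt = exp(rnorm(1, 0, 0.05)),
      amp_ml = exp(rnorm(1, 0, 0.05)),
      amp_ap = exp(rnorm(1, 0, 0.05)),
      # individuals differ substantially in how variable their gait is;
      # shared across a participant's runs so pairing is preserved
      jitter_timing = exp(rnorm(1, 0, 0.3)),
      jitter_amp = exp(rnorm(1, 0, 0.3)),
      speed = exp(rnorm(1, 0, 0.05)),
      height_m = rnorm(1, 1.73, 0.09),
      mass_kg = rnorm(1, 70, 10.5),
      age_yr = rnorm(1, 33, 11)
    ))
    e_p <- design$effect_scale *
      (if (proto == 3L) 1 - design$test_effect_attenuation else 1)
    conditions <- switch(as.character(proto),
      "1" = "treadmill", "2" = "sidewalk", "3" = c("treadmill", "sidewalk"))
    for (cond in conditions) {
      rseed <- derive_seed(design$seed, pid, cond)
      archetype <- if (cond == "treadmill") "consistent" else "variable"
      sp <- condition_speed(cond, e_p)
      speed <- with_seed(derive_seed(rseed, "speed"),
        pe$speed * rnorm(1, sp["mean"], sp["sd"]))
      speed <- max(speed, 1.5)
      mount <- with_seed(derive_seed(rseed, "mount"), list(
        tilt = rnorm(2, 0, 4), heading = runif(1, -15, 15)
      ))
      cfg <- make_archetype(
        archetype, e_p,
        duration_s = if (cond == "treadmill") duration_s else duration_s / speed,
        n_segments = if (cond == "treadmill") 1 else 2,
        speed_mps = speed,
        tilt_deg = mount$tilt, heading_deg = mount$heading,
        slow_mod_amp = if (cond == "sidewalk") 0.15 * e_p else 0
      )
      run <- generate_run(cfg, rseed,
        participant_effects = pe[c(
          "period", "amp_vt", "amp_ml", "amp_ap",
          "jitter_timing", "jitter_amp"
        )],
        participant = pid, condition = cond,
        keep_truth_signal = keep_truth_signal
      )
      runs[[length(runs) + 1]] <- run
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        participant = pid, protocol = proto, condition = cond,
        role = if (proto == 3L) "testing" else "training",
        speed_mps = speed, height_m = pe$height_m, mass_kg = pe$mass_kg,
        age_yr = pe$age_yr, seed = rseed
      )
    }
  }
  structure(
    list(runs = runs, manifest = dplyr::bind_rows(manifest), design = design),
    class = "gait_dataset"
  )
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf(
    "<gait_dataset> %d runs, %d participants (%d training / %d testing rows)\n",
    length(x$runs), dplyr::n_distinct(x$manifest$participant),
    sum(x$manifest$role == "training"), sum(x$manifest$role == "testing")
  ))
  invisible(x)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, paste(signif(unlist(x[[nm]]), 5), collapse = ", ")))
  invisible(x)
}
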