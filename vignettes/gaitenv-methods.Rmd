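---
title: "Methods: discriminating running environments from center-of-mass accelerations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating running environments from center-of-mass accelerations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gaitenv` classifies whether a run took place on a treadmill or on an outdoor
sidewalk, using only the tri-axial acceleration of a sensor worn near the
center of mass. This vignette documents the model behind each stage, the
tunable parameters and why their defaults are what they are, what the
synthetic data do and do not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer.

## The signal model of the synthetic generator

Running center-of-mass acceleration is quasi-periodic: one pulse per step,
alternating feet, with stride-to-stride fluctuations in both timing and
magnitude. The generator reproduces exactly this structure and nothing more:

* Step *i* lasts `T_i = T0 (1 + eta_i)`, `eta_i ~ N(0, sigma_t^2)`, alternating
  left/right feet.
* Within a step (normalized time `u` in `[0,1)`): the vertical (VT) pulse is
  `a_VT m_i sin(pi u)`, the anterior-posterior (AP) pulse is biphasic
  `a_AP m_i sin(2 pi u)` (braking then propulsion), and the medio-lateral (ML)
  pulse is `s_i a_ML m_i sin(pi u)` with the sign `s_i` alternating by stance
  foot — this is what makes ML repeat at the stride, not the step.
* `m_i = (1 + eps_i)(1 ± gamma)`: per-step amplitude noise
  (`eps_i ~ N(0, sigma_a^2)`) times a left/right asymmetry `gamma`.
* Gravity (9.81 m/s²) is added along the true vertical, the signal is rotated
  into the sensor frame by a planted tilt (roll, pitch) and heading, and white
  noise is added. The alignment stages therefore have real work to do, and
  planted rotations are recoverable ground truth.

Pulse shapes are deliberately schematic (half/full sines rather than fitted
waveforms): the downstream features measure periodicity, asymmetry, axis
energy shares and variability, all of which this model carries, and no
feature in the set depends on waveform details beyond that.

### Archetypes and cohorts

Two parameter presets encode the planted condition contrast. The *consistent*
(treadmill-like) archetype has lower timing jitter (0.015 vs 0.045 at effect
scale 1, around a common base of 0.03), lower amplitude jitter (0.03 vs 0.09),
a larger vertical amplitude (11 vs 9 m/s²) and a smaller AP amplitude
(2.98 vs 4.03 m/s²) than the *variable* (overground-like) archetype. All four
differences scale linearly with `effect_scale` and vanish at 0, which makes
the null cohort exchangeable between conditions — the property the
calibration tests rely on. The magnitudes themselves are free choices: they
were set once so that each planted contrast is comfortably measurable in a
five-minute run, and they produce the qualitative pattern expected of this
contrast (more vertical energy and higher regularity on the treadmill, more
AP energy and higher magnitude variability overground).

`generate_cohort()` reproduces a three-protocol design: 28 participants run
only in the consistent environment, 25 only in the variable environment
(together the training data), and 16 run in both (the independent testing
data). Protocol-level structure is applied on top of the archetypes:

* **Durations.** Treadmill runs are one 300 s segment; sidewalk runs are two
  independently generated 300 m legs (duration `300 / speed` each), each leg
  trimmed separately, mirroring an out-and-back course with a pause at the
  turnaround.
* **Speeds.** Treadmill speed ~ N(2.78, 0.26) m/s; sidewalk speed
  ~ N(2.78 + 0.46 e, 0.26 + 0.16 e) with `e = effect_scale`, so at `e = 1`
  the sidewalk analog averages 3.24 (0.42) m/s and at `e = 0` the speed
  distributions coincide (otherwise speed alone would break the null).
* **Non-stationarity.** Sidewalk amplitudes are modulated by a slow 0.05 Hz
  sinusoid of relative depth `0.15 e`, a stand-in for inclines and curves.
* **Random effects.** Each participant draws one set of log-normal
  multipliers, shared across that participant's runs: SD 0.05 on step period,
  per-axis amplitudes and speed, and SD 0.3 on the two jitter parameters.
  The latter is essential realism: individuals differ far more in *how
  variable* their gait is than in its average magnitude, and without that
  spread the variability features separate the conditions perfectly and the
  whole selection/classification problem collapses to a single feature with
  zero overlap.
* **Reproducibility.** Every run's RNG stream is derived from
  (cohort seed, participant id, condition), so enlarging a cohort never
  changes existing runs, and everything is bit-reproducible from the seed.

What the generator does **not** emulate: ground-reaction-force realism,
musculoskeletal dynamics, foot-strike transients above 10 Hz, surface
irregularity beyond the slow modulation, GPS/altitude structure, or sensor
drift and calibration error. Passing tests therefore demonstrate that the
pipeline recovers planted structure of the kinds listed above — not that it
would achieve any particular accuracy on real runners.

## Preprocessing

Order: filter → trim → gravity alignment → heading alignment, each behind its
own function.

* **Filter.** 4th-order low-pass Butterworth at 10 Hz, applied forward and
  backward (zero phase) so contact timing is not biased; the effective
  attenuation is therefore doubled. `signal::filtfilt` assumes zero initial
  conditions, so each segment is mean-removed and padded by odd reflection
  (1.5 s) before filtering; without this, segment edges carry large
  transients. Cutoffs at or above Nyquist are rejected.
* **Trim.** `floor(0.05 × length)` samples from each end of *each* segment
  independently (each sidewalk leg separately); a trimmed segment shorter
  than 2 s is rejected.
* **Gravity.** The rotation taking the mean acceleration direction onto the
  vertical (quasi-static assumption — over whole steps the dynamic terms
  average nearly to zero). The per-segment VT mean (gravity plus mean dynamic
  lift) is then subtracted, so VT is zero-mean per segment by construction.
  A mean acceleration below 5 m/s² is rejected as "not capturing gravity".
* **Heading.** Principal-axis rotation of the horizontal plane so AP carries
  the dominant variance; the forward sign is set so the AP skewness is
  non-negative, and ML follows to keep the frame right-handed. Two caveats
  are inherent: a purely biphasic AP pattern has zero skewness, so on the
  synthetic signal the forward sign is genuinely unidentifiable (tests accept
  a 180° flip), and isotropic horizontal variance (within 1e-12) leaves the
  rotation at identity with a warning. Rotations are orthonormal and preserve
  per-sample resultant magnitudes to 1e-9.

## Step segmentation

The dominant step period is the first local maximum (at least half the band
maximum, coefficient > 0.1) of the unbiased VT autocorrelation in the
physiological band 0.25–1.0 s. Taking the *first* qualifying peak rather than
the global maximum keeps asymmetric gaits (whose stride peak can edge above
the step peak) from returning the stride period.

Contacts are local VT maxima above the 60th percentile separated by at least
half the period, each then refined to the VT minimum since the previous peak:
on a pulse-train signal that valley is the pulse onset, which is what the
planted truth records; the mid-stance peak sits roughly half a step later.
The detector is isolated behind `detect_initial_contacts()` so a different
event-detection scheme can be swapped in.

Steps are intervals between consecutive contacts within one segment. Three
guards apply before the 50-point linear resampling:

* durations outside `[0.25, 1.25] ×` the dominant period are excluded — in
  particular the double-length interval left by a missed contact;
* the first and last step of every segment are excluded: after trimming, a
  partial pulse survives at each segment edge and its contact placement is
  unreliable. Without this guard, two-segment runs (four edges) acquire a
  small systematic inflation of timing variability relative to one-segment
  runs, which is pure protocol structure, not gait;
* fewer than 30 detected contacts is an error (stride-lag regularity needs a
  reasonable number of strides).

Strides pair two consecutive retained steps; linear interpolation is used for
the 50-point normalization because it is shape-preserving and exact for
linear segments.

## Features

All 25 features and their definitions are listed in `?feature_names`. The
numerical conventions that matter:

* Regularity/RMS quantities use the continuous aligned signal at its original
  time base (autocorrelation at a stride lag is meaningless on time-normalized
  steps); per-step peaks and per-step RMS come from the 50-point matrix.
* Each axis is mean-removed **per segment**, and regularity is the
  length-weighted mean of per-segment autocorrelations. Correlating across
  the junction of concatenated segments mixes unrelated phases and
  systematically depresses regularity for two-segment runs — the same
  protocol-leak issue as the edge steps, and the reason this choice is not
  left to taste.
* Lags are the mean step/stride durations rounded to the nearest sample.
* Symmetry is the ratio (step over stride regularity); 1 means left/right
  symmetric. On the ML axis, step-lag regularity is negative by construction
  (alternating feet), so ML symmetry is also negative and "higher" is not a
  meaningful direction there.
* The unbiased autocorrelation estimator can marginally exceed 1 on a
  perfectly periodic signal (its numerator averages fewer terms than its
  denominator); regularities are clipped to `[-1, 1]` in the assembled
  feature vector. The raw estimator is left unclipped and is tested against
  an O(n²) brute-force oracle.
* The squared RMS ratios sum to one exactly because the resultant is computed
  from the same mean-removed axes as the per-axis RMS values.

## Selection and classification

The LDA wrapper is a two-class pooled-covariance discriminant with equal
priors, written directly (it is fitted ~10⁵ times per selection run); a
singular pooled covariance gets a 1e-8 ridge with a warning, and the
implementation is cross-checked against an independent reference in the test
suite. Fold construction is participant-wise and condition-stratified;
"subject-wise" selection is read as: no participant's rows may straddle a
fold boundary. Forward selection adds the error-minimizing candidate, breaks
ties by canonical feature order (the order of `feature_names()`), and stops
when no candidate *strictly* reduces the CV error — with the consequence that
on pure-noise tables a few spurious features can still chain together; what
is guaranteed there is chance-level error and unstable retention, and that is
what the tests assert. The 10%-of-iterations retention boundary is inclusive.
Randomness across the 100 iterations is confined to the fold partitions.

The SVM is `e1071::svm` with an RBF kernel; cost and gamma are tuned by an
inner stratified 5-fold grid search over `10^-3 … 10^3` (ties to the smaller
cost, then smaller gamma), on features standardized by training statistics,
then refit on all training rows. Accuracy is row-level; the treadmill-analog
label is the fixed positive class. Per-iteration fold assignments are stored
on the result so leakage can be audited after the fact.

Speed is a candidate feature like any other; at effect scale 1 it carries
real signal (the planted cohort speed contrast), and whether it is retained
depends on the competing features in a given cohort.

## Statistics

Retained features are compared with Welch t-tests on the training cohort
(equal variances are not assumed) and paired t-tests on the testing cohort,
with Bonferroni control at `alpha / m`, `m = 2 ×` the number of retained
features. Shapiro–Wilk p-values are reported alongside for inspection, with
no automatic nonparametric fallback. Cohort descriptives (height, mass, age,
per-condition speed) are compared across protocols by one-way ANOVA, plus a
paired t-test on the both-condition group's speeds; identical-value
degenerate cases return F = 0, p = 1. Only the feature family is
Bonferroni-adjusted; the descriptive ANOVAs are reported raw.

## Problem sizes and scope of the test suite

Unit tests run on 30–60 s single runs and small cohorts; the end-to-end
calibration tests and the acceptance script use the full study-scale design
(28/25/16 participants, 300 s treadmill runs, two 300 m sidewalk legs) with
100 selection iterations, and 20–100 classification iterations. Monte-Carlo
assertions (direction of planted contrasts, null calibration within
50% ± 10%, detector hit rates ≥ 95%) use ≥ 20 seeded replicates. These sizes
were chosen so the planted effects are measured with comfortable margins at
desk scale.

## Known limitations

* The step detector assumes one dominant positive VT pulse per step; gaits
  with double peaks per step (pronounced impact + active peaks) would need a
  different detector behind the same interface.
* The heading sign convention relies on AP skewness and is undefined for
  perfectly symmetric AP waveforms (as in the generator).
* Feature values depend on the stated conventions (gravity/mean removal,
  per-segment regularity, across-step RMS CV); alternative readings of
  "RMS CV" (within-step) would change scales.
* Synthetic validation bounds what can be claimed: the pipeline recovers
  planted structure; no claim about accuracy on human data is made or
  testable here.
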