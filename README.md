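# gaitenv

Classifying running environment (treadmill vs. overground sidewalk) from
center-of-mass accelerometry.

Most running biomechanics data are collected on treadmills, but most running
happens outdoors, and gait differs between the two. `gaitenv` implements a
complete, testable pipeline for deciding — from a single lower-back IMU —
which environment a run took place in: preprocessing of raw tri-axial
accelerations, step segmentation, a 25-feature description of the gait
pattern, wrapper feature selection, and participant-wise cross-validated SVM
classification with evaluation on an independent cohort. Because raw cohort
data of this kind are rarely shareable, the package ships a synthetic cohort
generator with planted, controllable gait structure, so every stage of the
pipeline can be validated against known ground truth.

## The method

**Signals.** Tri-axial accelerations (sensor frame: x right, y vertical,
z posterior; 201.03 Hz) are low-pass filtered (4th-order Butterworth, 10 Hz,
zero-phase), trimmed by 5% at each end of every recording segment, rotated so
the vertical (VT) axis matches the mean acceleration direction (gravity) and
the anterior-posterior (AP) axis carries the dominant horizontal variance,
then segmented into steps at initial contacts; each step is time-normalized
to 50 points.

**Features (25).** Mean speed; step- and stride-time CVs; resultant RMS; and
per axis a ∈ {AP, ML, VT}: step and stride regularity, symmetry, peak, RMS,
RMS CV, and RMS ratio. Regularity is the unbiased autocorrelation of the
mean-removed axis signal at the mean step/stride lag,

```
A(x, L) = [ Σ_t x_t x_{t+L} / (n − L) ] / [ Σ_t x_t² / n ],
```

symmetry is step over stride regularity, the RMS ratio is the axis RMS over
the RMS of the per-sample resultant (so the squared ratios across axes sum to
one), and the RMS CV is the across-step coefficient of variation of per-step
RMS.

**Selection.** Subject-wise forward-sequential feature selection with a
two-class LDA wrapper scored by participant-wise 10-fold cross-validation,
repeated over 100 fold partitions; features selected in at least 10% of
iterations are retained and ranked by mean selection order.

**Classification.** An RBF-kernel SVM (box constraint and kernel parameter
tuned by an inner 5-fold grid search over 10⁻³…10³) is evaluated two ways,
over repeated iterations: participant-wise 10-fold CV of the training cohort,
and prediction of an independent cohort that ran in both environments.
Retained features are compared between conditions with Welch (training) and
paired (testing) t-tests under Bonferroni control.

## Worked example

```r
library(gaitenv)

cfg <- pipeline_config(n_treadmill_only = 8, n_sidewalk_only = 8, n_both = 4,
                       duration_s = 90, n_iterations_selection = 25,
                       n_iterations_classify = 10)
res <- run_pipeline(cfg, seed = 42)

res$selection
#> <selection_result> 25 iterations, 1/25 features retained (threshold 10%)
#>   step_time_cv           mean rank 1.00  retained in 100%

res$evaluation
#> <eval_result> 10 iterations on 1 features
#>   training 10-fold CV accuracy: 98.12% (SD 3.02%)
#>   independent test accuracy:    100.00% (SD 0.00%)

dplyr::select(res$comparisons, feature, dataset, statistic, p_value, significant)
#> # A tibble: 2 × 5
#>   feature      dataset  statistic   p_value significant
#>   <chr>        <chr>        <dbl>     <dbl> <lgl>
#> 1 step_time_cv training      8.26 0.0000399 TRUE
#> 2 step_time_cv testing       9.14 0.00277   TRUE
```

At this small scale the generator's planted contrast (a consistent,
treadmill-like regime vs. a more variable overground regime) is carried most
strongly by step-timing variability: selection retains `step_time_cv`, the
classifier separates the two environments almost perfectly, and the retained
feature differs significantly between conditions in both cohorts at the
Bonferroni-adjusted threshold. `autoplot(res$selection)` and
`autoplot(res$evaluation)` visualize retention frequencies and accuracy
distributions; `tidy()`/`glance()` return the same information as tibbles.

Single runs can be inspected at any stage: `generate_run()` →
`preprocess_run()` → `segment_steps()` → `extract_feature_vector()`, with
`plot_aligned_signal()` for the aligned traces. Cohorts round-trip to disk as
CSV + JSON sidecars via `write_cohort()` / `load_dataset()`.

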