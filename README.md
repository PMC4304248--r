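# aeegrf

Automatic classification of amplitude-integrated EEG (aEEG) background
patterns with a class-weighted random forest.

aEEG is the filtered, rectified, smoothed and time-compressed EEG trend
trace produced by bedside cerebral function monitors and used for long-term
brain monitoring of critically ill newborns. Experienced clinicians read
the 3-hour trace and call its background *normal* (continuous activity,
lower margin above ~5 µV, roughly Gaussian amplitude histogram) or
*abnormal* (burst suppression, low voltage, flat trace — irregular or
bimodal histograms, depressed lower margin). `aeegrf` is for researchers in
neonatal neuromonitoring and biomedical signal processing who want that
call automated, reproducible, and open to inspection.

## What the package computes

**Combined 119-dimensional feature set.** From each rectified amplitude
trace u(t) (µV):

* 4 *basic* features — min, max, mean amplitude, and the percentage of the
  recording-level second-order lower envelope below 5 µV;
* 55 *histogram* features — amplitude proportions in 1 µV bins over
  [0, 50) µV and 10 µV bins above (last bin open-ended);
* 60 *segment* features — the trace is cut into 3-min windows stepped by
  1.5 min; each segment contributes its upper/lower boundary (mean of the
  second-order envelope), mean, and approximate entropy
  ApEn(m, r, N) = Φ_m(r) − Φ_{m+1}(r), with
  Φ_m(r) = (N−m+1)⁻¹ Σᵢ ln Cᵢᵐ(r) and Cᵢᵐ(r) the fraction of m-length
  templates within Chebyshev distance r of template i. The segments with
  the 10 highest and 5 lowest ApEn values are kept: 15 × 4 = 60 features.

**Class-weighted random forest**, implemented from scratch: bagging,
per-node random draws of m_try = round(√p) candidate features, splits
maximizing the decrease of the weighted Gini impurity
1 − Σ_k p_k² with p_k = w_k n_k / Σ_j w_j n_j, fully grown unpruned trees,
weighted leaf votes, out-of-bag (OOB) error estimation, and
permutation-based feature significance (per-tree drop in correct OOB votes
after permuting one feature, averaged over trees). Class weights
(default abnormal:normal = 3:1) enter the Gini criterion and the vote,
making the forest cost-sensitive on imbalanced cohorts; tuning sweeps for
forest size, m_try and the weight ratio are built in, scored by OOB error
and the G-mean √(sensitivity × specificity).

**Synthetic cohort generator.** Clinical aEEG recordings are not shipped;
`make_dataset()` synthesizes labeled traces (normal continuous background;
burst-suppression, low-voltage, and flat abnormal patterns) with
per-recording parameter jitter, deterministic under a master seed, so the
entire pipeline is testable end to end.

## Worked example

```r
library(aeegrf)

cfg  <- synthesis_config(duration_s = 10800, seed = 42)
recs <- make_dataset(n_normal = 30, n_abnormal = 10, cfg)
recs[[1]]
#> <aeeg_recording 'normal_001'> 10800 samples @ 1 s (10800.0 s total), label: normal

round(extract_combined(recs[[1]])[1:4], 2)
#>            basic_min            basic_max           basic_mean basic_pct_low_margin
#>                 6.45                27.30                17.16                 0.00

ds  <- extract_dataset(recs)      # 40 x 119 feature matrix + labels
fit <- rf_fit(ds$x, ds$labels, forest_config(n_tree = 200, seed = 1))
fit
#> <aeeg_forest> 200 trees, m_try = 11, weights abnormal=3 normal=1, 40 training samples

oob_error(fit, ds$x, ds$labels)   # internal unbiased test-error estimate
#> OOB error: 0.000

op <- oob_predict(fit, ds$x)
compute_metrics(confusion_counts(ds$labels, op$class))
#> correct rate 100.00%  sensitivity 100.00%  specificity 100.00%  F1 100.00%  G-mean 100.00%  (n = 40, positive = abnormal)

imp <- permutation_importance(fit, ds$x, ds$labels, seed = 1)
head(imp[order(-imp$importance), ], 3)
#>                 feature importance
#> 4  basic_pct_low_margin 0.03583681
#> 23             hist_018 0.02853667
#> 17             hist_012 0.02745297
```

The first recording is a normal trace: its lower envelope never drops
below 5 µV (`basic_pct_low_margin = 0`) and its mean sits near 17 µV. The
forest separates this synthetic cohort perfectly out-of-bag (synthetic
classes are cleaner than clinical ones — see the vignette), and the
permutation significance ranks the depressed-lower-margin percentage
first, matching the clinical reading of abnormal background.

The same pipeline is scriptable from a shell via
`Rscript $(Rscript -e 'cat(system.file("cli/aeegrf.R", package="aeegrf"))')`
with subcommands `simulate`, `extract`, `train`, `predict`, `evaluate`,
`tune`, `importance`.

## Documentation

The methods vignette (`vignettes/aeeg-classification.Rmd`) describes the
model, its parameters and defaults, the synthetic-data design, numerical
conventions, and known limitations.
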