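---
title: "Classifying aEEG background patterns with a class-weighted random forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying aEEG background patterns with a class-weighted random forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Amplitude-integrated EEG (aEEG) condenses hours of neonatal EEG into a
slow amplitude-envelope trace that clinicians read at the cot side. The
background pattern of that trace — continuous normal-voltage activity
versus burst suppression, persistently low voltage, or a flat trace — is
one of the strongest available predictors of neurological outcome in
critically ill newborns. `aeegrf` implements an automatic reader: a fixed
119-dimensional feature description of a nominal 3-hour trace, and a
cost-sensitive random forest that classifies it normal/abnormal. This
vignette is the package's own account of the method: the model, the
parameters that matter, the synthetic data the tests run on, numerical
conventions, and the limits of what the shipped experiments demonstrate.

## The feature model

The input is a rectified amplitude series in microvolts (non-negative,
finite, at least two samples), with a constant sample interval — 1 Hz by
default, appropriate for the time-compressed aEEG envelope. Three feature
blocks are concatenated in a fixed order into 4 + 55 + 60 = 119 named
features.

**Basic features (4).** Minimum, maximum and mean amplitude, plus the
percentage of the recording-level *second-order lower envelope* lying
strictly below 5 µV. The 5 µV lower-margin rule is the classical
bedside criterion: a healthy term infant's lower margin stays above it,
while suppressed backgrounds spend most of their time below.

**Histogram features (55).** Proportions of samples in amplitude bins:
1 µV bins over [0, 50) — the range where clinical discrimination happens —
and 10 µV bins from 50 µV up, the last bin open-ended `[90, Inf)` so no
sample is ever dropped. A sample at exactly 50.0 µV belongs to [50, 60).
Proportions rather than counts keep recordings of different lengths
comparable; they sum to 1 by construction. Normal backgrounds produce a
unimodal, roughly Gaussian histogram; burst suppression a bimodal one;
low-voltage traces pile mass into the lowest bins.

**Segment features (60).** The trace is segmented with a 3-minute window
stepped by 1.5 minutes (50 % overlap), giving
`floor((L - 180)/90) + 1` segments — 119 for a 10,800 s recording. Each
segment yields four values: the means of its second-order upper and lower
envelopes (the segment's upper/lower boundary), its mean amplitude, and
its approximate entropy. Segments are then ranked by ApEn and only the 10
highest- and 5 lowest-ApEn segments are kept (ties broken toward the
earlier segment), because extremes of irregularity *or* regularity are
the stretches most likely to betray an abnormal background. Output order
is top rank 1–10 then bottom rank 1–5, four values each: 60 features.

### Approximate entropy

For a series u(1), …, u(N), embedding length m and tolerance r, define
template vectors X_i = (u(i), …, u(i+m−1)) and

C_i^m(r) = (N−m+1)^{-1} · #{ j : max_k |u(i+k) − u(j+k)| ≤ r },

Φ_m(r) = (N−m+1)^{-1} Σ_i ln C_i^m(r), and
ApEn(m, r, N) = Φ_m(r) − Φ_{m+1}(r).

The package uses the standard conventions: Chebyshev distance,
self-matches included (so every count is positive and ApEn is finite and
non-negative), m = 2, and r = 0.2 × the SD of the segment being analyzed.
A zero-variance segment has no scale, so the tolerance falls back to
1 µV there; its ApEn is exactly 0 regardless. All of m, r and the
selection counts are configuration, not constants. The implementation is
O(N²) in compiled code and is tested for 1e-12 agreement against an
independent nested-loop evaluation on a suite of short series.

### The second-order envelope

No closed construction is standard for "the" envelope of a sampled trace,
so the package commits to one: a single pass marks all local maxima
(non-strict comparisons, endpoints always included) and linearly
interpolates through them; a second identical pass over that envelope
gives the second-order upper envelope, and symmetrically for minima. Two
passes smooth single-sample noise spikes that a first-order envelope
would chase, which matters because the 5 µV margin feature and the
segment boundaries are read off this curve. For a constant series both
envelopes equal the series, so a constant 3 µV trace scores 100 % below
the margin and a constant 20 µV trace 0 %.

## The classifier

The forest is written from scratch because the weighting scheme is the
point: class weights w_k enter in exactly two places, the split criterion
and the vote — not the bootstrap.

* **Bagging.** Each of `n_tree` trees (default 1000) is grown on a
  uniform size-n bootstrap; membership is stored per tree, so roughly
  e^{-1} ≈ 37 % of samples are out-of-bag for each tree.
* **Split search.** At every node a fresh subset of
  `m_try = round(sqrt(p))` features (11 at p = 119) is drawn without
  replacement. Candidate thresholds are midpoints of consecutive distinct
  sorted values. The chosen split maximizes the decrease in weighted Gini
  impurity, 1 − Σ_k p_k² with p_k = w_k n_k / Σ_j w_j n_j, children
  weighted by their share of weighted mass. Ties resolve to the lowest
  feature index, then the lowest threshold, so fits are deterministic.
* **Fully grown trees.** Recursion stops only at purity, fewer than two
  samples, or no impurity-reducing split; no depth cap, no pruning.
* **Weighted vote.** Leaves store p_k = w_k n_k / Σ w_j n_j. Prediction
  averages these vectors over trees and takes the argmax; exact ties go
  to *abnormal*, the minority class with the higher misclassification
  cost. A hard per-tree vote mode exists behind `vote_mode = "vote"`;
  the two differ only on near-ties. With unit weights the machinery
  reduces exactly to a plain unweighted forest.
* **OOB estimation.** A sample is scored by the trees that did not see
  it; samples in every bootstrap (possible only in tiny forests) are
  excluded from the error denominator.
* **Permutation significance.** Per tree, the correct-OOB-vote fraction
  is compared before and after permuting one feature within the OOB set;
  the mean over trees is the feature's raw significance. Per-tree votes
  are hard class calls here, regardless of the forest's vote mode.

Reproducibility is structural: every tree derives its own seed from
(master seed, tree index), so fits do not depend on evaluation order, and
fit/predict/OOB/importance are bit-reproducible under a fixed seed.
Models serialize to a versioned JSON schema (config, feature names, flat
node arrays, bootstrap indices); a reloaded forest reproduces predictions
exactly.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_s`, `step_s` | 180 s, 90 s | segment length and step; 50 % overlap |
| `m`, `r_frac` | 2, 0.2 | ApEn embedding length; tolerance as fraction of segment SD |
| `n_top`, `n_bottom` | 10, 5 | ApEn-ranked segments kept |
| `n_tree` | 1000 | forest size; OOB error stabilizes well before this |
| `m_try` | round(√p) = 11 | candidate features per node |
| `class_weights` | abnormal 3 : normal 1 | cost ratio in Gini and vote |
| `min_leaf` | 1 | minimum child size (fully grown trees) |

The 3:1 default reflects the tuned operating point for a roughly 3:1
imbalanced cohort; `sweep_class_weight()` re-derives a recommendation on
any dataset by maximizing the OOB G-mean
√(sensitivity × specificity), which is maximal only when both rates are
high and is insensitive to the class split. On strongly separable data
the sweep is flat at G-mean 1 and recommends the smallest ratio — weights
only move the operating point when the classes actually collide.

A note on segment counts: with the stated 3-min/1.5-min scheme a 3-hour
trace yields 119 segments (and 119 × 4 = 476 segment values before
selection). Descriptions of this scheme sometimes quote 80 segments per
3-hour trace, which is inconsistent with that window/step arithmetic; the
package follows the arithmetic. The selected 60- and combined
119-dimension counts are unaffected, and window, step and selection
counts are all configurable if a different reading is wanted.

## Synthetic data: what it emulates and what it does not

Clinical aEEG recordings cannot be shipped, so the package generates
cohorts whose *feature-level* structure matches what the classifier
consumes:

* **normal** — baseline 16 µV plus a slow sinusoid (period 3600 s,
  bandwidth 8 µV) emulating sleep–wake cycling, plus Gaussian noise
  (SD 2 µV), clipped at zero. Unimodal, roughly symmetric histogram;
  lower envelope essentially always above 5 µV.
* **burst_suppression** — a 2 µV suppressed baseline interrupted by
  Gaussian-shaped bursts (40 µV nominal, ~3 s wide) arriving as a Poisson
  process at 3/min. Overlapping bursts combine by maximum, since an
  amplitude envelope does not stack coincident bursts. Bimodal histogram;
  depressed lower envelope.
* **low_voltage** — the normal model scaled down (baseline 3 µV,
  bandwidth 2 µV, noise 0.8 µV): continuous but persistently low, lower
  envelope almost entirely below 5 µV.
* **flat** — near-isoelectric, 1.5 µV with 0.15 µV noise.

Each recording multiplies its class parameters by lognormal jitter
(SD 0.08–0.3 on the log scale) drawn from its own seed, emulating
between-infant variability; the normal-class jitter is kept tight enough
that the 5 µV margin property holds with margin across seeds. Datasets
are pure functions of (counts, config, master seed); abnormal subtypes
rotate round-robin.

What this does **not** emulate: semi-logarithmic display compression,
electrode artifacts (movement, sweating, impedance excursions), seizure
activity, sleep-stage microstructure, or the genuinely ambiguous
borderline tracings that make the clinical problem hard. The synthetic
classes are well separated in feature space, so the shipped forest
reaches OOB correct rates near 100 % — the tests demonstrate that the
pipeline is *correct* (features computed as specified, weighting and OOB
machinery behaving as theory predicts), not that the method achieves any
particular accuracy on clinical data, whose headline performance can only
be re-established on a clinical cohort.

## Numerical conventions and degenerate inputs

* Splits require an impurity decrease above 1e-12; "no improving split"
  ends recursion, so constant-feature nodes become leaves.
* A recording shorter than the analysis duration warns rather than
  errors (small fixtures are legitimate); shorter than one window, or
  fewer than `n_top + n_bottom` segments, errors — selection never
  silently truncates.
* Histogram bins are half-open [a, b); amplitudes are validated
  non-negative and finite at construction.
* ApEn requires N ≥ m + 2 and r > 0, and errors otherwise; segment-level
  failures are re-raised with the segment index attached.
* Metrics with zero denominators (e.g. F1 with no predicted positives)
  are returned as `NA`, never silently 0.
* Stratified k-fold assignment shuffles within class, then deals
  round-robin with the fold position carried across classes, keeping
  both class proportions and overall fold sizes within one sample.
* Sweeps average 5 seeded repeats per grid point to tame OOB noise at
  small `n_tree`.

The shipped experiments run at reduced problem sizes chosen to exercise
every code path at full recording length where length matters: 3-hour
recordings for structural counts, cohorts of 135–185 recordings for the
forest properties, 200-tree forests for the weight sweeps.

## Known limitations

* Two classes only. The formulas generalize to k classes but the package
  validates and tests the binary normal/abnormal task.
* The EDF reader is a minimal single-channel EDF/EDF+ implementation
  (16-bit integer samples, physical scaling, annotation channels
  skipped); exotic EDF variants are out of scope, and CSV is the
  canonical format.
* No artifact rejection or impedance screening: the package assumes its
  input is an already-clean aEEG amplitude trace.
* Training is single-threaded by design — determinism under a master
  seed is guaranteed by per-tree derived seeds, and typical cohort sizes
  fit comfortably.
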