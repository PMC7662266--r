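---
title: "Classifying gait patterns from smart-shoe sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gait patterns from smart-shoe sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartgait)
```

## The problem

Abnormal gait — habitual supination (toe-out), pronation (toe-in) or an
unstable left or right foot — is an early marker of foot disorders, and a
pair of instrumented shoes is one of the few ways to observe it during
natural walking. The instrument modelled here carries, per shoe, four
plantar pressure sensors (heel, lateral midfoot, medial forefoot, toe), a
three-axis accelerometer and a three-axis gyroscope: 20 channels in total.
`smartgait` implements the full analysis chain from those raw channels to a
five-class gait-pattern classifier, and benchmarks which sensors, which
gait-cycle segmentation and how many principal components the classifier
actually needs — the questions that decide what a low-cost production shoe
must carry.

The pipeline is:

1. **Event detection** — a foot is in ground contact when any of its four
   pressure channels reaches a threshold (40 ADC units); contact onsets are
   heel strikes, offsets toe-offs.
2. **Segmentation** — recordings are cut under seven gait-cycle schemes:
   stride, step, stance, swing, left/right single limb support, double limb
   support.
3. **Feature extraction** — ten statistics per channel (mean, SD, kurtosis,
   crest factor, skewness, entropy, spectral flux, power, zero crossings,
   maximum) plus 24 within-shoe same-sensor Pearson correlations: 224
   columns.
4. **Feature selection** — information-gain ranking, and a fixed retention
   rule that drops the 52 low-information columns (power on the 12 inertial
   channels, all zero-crossing and maximum columns), keeping 172.
5. **Feature reduction** — standardization to zero mean / unit variance,
   then PCA keeping the smallest number of components whose cumulative
   explained variance reaches 99%.
6. **Classification** — SVM (RBF kernel, C = 1, gamma = "scale"), random
   forest (100 trees, Gini, min split 15, max depth 30), kNN (k = 5) and
   multinomial logistic regression, evaluated with leave-one-participant-out
   cross-validation (LOOCV) and weighted precision/recall.

Because the treadmill cohorts such pipelines are developed on are generally
not public, the package ships a synthetic cohort generator that plays the
role of the recording hardware: every downstream stage is developed and
tested against simulated recordings whose ground truth is known exactly.

## The synthetic cohort

`simulate_cohort()` emulates a treadmill protocol: per participant, 3 min of
normal walking and 1 min of each abnormal gait (180 s / 60 s defaults),
sampled at 100 Hz. Neither a sampling rate nor pressure units are dictated
by the problem; we use 100 Hz and ADC-like units on [0, 1023], which makes
the conventional contact threshold of 40 meaningful out of the box
(baseline noise mean + 5 SD stays below 40, burst peaks are an order of
magnitude above it).

Each gait class is a small parameter vector (`class_signature()`):

* stance fraction per foot (normal 0.60 — the usual ~60/40 stance/swing
  split);
* heel-to-metatarsal contact gap (normal 0.12 s; supination shortens it to
  0.05 s, pronation — the opposite movement — lengthens it to 0.19 s);
* lateral share of forefoot load (0.50 normal; 0.75 supination; 0.65
  pronation). Note the pronation default follows the toe-in description in
  which the inward-turned toes shift weight to the *outside* of the foot;
  users who prefer the conventional medially-loaded definition of pronation
  can override `lateral_weight_share` below 0.5 — the direction is a plain
  parameter, not a hard-coded assumption;
* step-length scale per foot (an unstable foot takes a 25% shortened step
  and its stance fraction deviates: 0.52 vs the other foot's 0.62).

These are qualitative clinical directions given definite numeric defaults
(roughly 15–30% deviations from normal), all overridable. Pressure bursts
are flat-topped with 30 ms half-cosine edges, timed per sensor within
stance (heel earliest, toe latest, the metatarsal sensor delayed by the
heel-metatarsal gap); the accelerometer carries a damped heel-strike impact
transient plus cycle-locked oscillation; the gyroscope a swing-phase
angular-velocity peak whose amplitude tracks the step-length scale, plus a
transverse component driven by the toe-angle parameters.

Variability enters at three levels, all seeded:

* **between participants** — cadence uniform on 55–65 strides/min, and
  log-normal multipliers on amplitude (sigma 0.10), sensor noise (0.15) and
  stance fraction (0.03); profiles are a pure function of
  (cohort seed, participant id);
* **between strides** — heel-strike timing jitter (SD 0.02 s), log-normal
  amplitude jitter (sigma 0.08) and stance-duration jitter (sigma 0.02),
  matching typical human stride-time and force coefficients of variation.
  This level is deliberately *independent* of the sensor-noise knob: a
  noiseless sensor still records a variable walker. It also matters
  statistically — without stride-to-stride variability every participant
  collapses to a point cluster in feature space and leave-one-participant-out
  evaluation degenerates;
* **within samples** — Gaussian sensor noise, scaled by the global
  `noise_scale` knob (1 = default; lower it for separability experiments).

What the generator does **not** emulate: treadmill-speed physics,
musculoskeletal dynamics, sensor drift or saturation artefacts, fatigue,
or the difficulty real participants have in mimicking an abnormal gait
consistently. Passing tests on synthetic cohorts therefore demonstrate that
the *pipeline* is correct and behaves sensibly (parameter recovery,
ordering properties, permutation nulls) — not that any particular real-data
accuracy would be reached. Real cohorts show substantially more overlap
between classes than the simulator's clean signatures do.

## Numerical and design choices

* **Segment indexing** — segments are half-open sample intervals
  `[start, end)` with 1-based indices (the R convention); the time of
  sample *i* is `(i - 1) / fs`. Stride, stance and swing are anchored on
  the right foot by default (configurable). Contact phases shorter than
  50 ms are debounced away; segments shorter than 4 samples are dropped
  (correlation and SD need several points).
* **Toe-off convention** — toe-off is the end of whole-foot contact under
  the any-sensor rule, giving a single unambiguous contact indicator per
  foot rather than per-sensor pre-swing events.
* **Kurtosis and skewness** — the conventional standardized moments
  (fourth/third central moment over SD to the fourth/third power). A
  `literal = TRUE` flag reproduces lower-exponent variants occasionally
  seen in print; they are not the default because the lower-exponent
  kurtosis is not scale-invariant and the squared "skewness" is a
  near-constant, neither of which a practitioner wants.
* **Spectral flux** — despite the name, defined here (as in its printed
  form) as the sum of squared successive sample differences within the
  segment: a time-domain statistic, one scalar per channel.
* **Entropy and information gain discretization** — 10 equal-width bins
  over the segment's (or feature's) own range; entropy in nats, information
  gain in bits (log base 2). These constants are not canonical — they are
  fixed here for reproducibility.
* **Degenerate segments** — zero-variance segments yield 0 for correlation,
  kurtosis, skewness and entropy (and crest factor when the RMS itself is
  0) instead of NaN, so a few flat segments cannot poison the PCA.
* **Retention rule** — the 52-column discard is hard-coded as a family rule
  (power on inertial channels, all zero-crossing and maximum columns),
  reproducing the information-gain-derived outcome deterministically;
  `discard_bottom_k()` offers the data-driven mechanism for experiments.
* **PCA fit scope** — reporting a single global component count leaks test
  information into the projection, so the default fits standardizer and PCA
  per training fold and picks k by the 99% rule per fold; `n_pcs` fixes k
  globally for sweep-style tables. Axes are oriented so the
  largest-magnitude loading is positive, making results backend-independent.
* **SVM gamma** — "scale" is implemented as `1 / (d * Var(X))` with
  `Var(X)` the variance of the pooled training matrix, the common library
  convention for RBF kernels.
* **0/0 precision** — a class never predicted in a fold gets precision 0
  with a warning, keeping weighted averages defined in every fold.
* **Column error rates** — per predicted-class column,
  `(column sum - diagonal) / column sum` as a percentage, averaged
  unweighted over the five classes; `reference_confusion_matrices()` ships
  five published per-participant worked examples that this convention
  reproduces exactly.
* **t-tests** — paired one-tailed t-tests pair per-participant (per-fold)
  metric values, the only pairing unit consistent with a LOOCV design;
  cross-fold SDs are sample SDs. Zero-variance differences are reported as
  p = 0.5 (no difference) or 0/1 with a degenerate flag rather than
  erroring.
* **Class imbalance** — normal walking contributes about three times the
  segments of each abnormal gait, mirroring the acquisition protocol; it is
  kept, not rebalanced, and the weighted metrics absorb it.

## A worked run

A reduced cohort (6 participants, 75 s normal / 25 s per abnormal gait —
the problem size also used by the package's acceptance script) runs the
whole chain in a few minutes on one CPU:

```{r pipeline, eval = FALSE}
cohort <- simulate_cohort(6, seed = 1,
                          durations_per_class = c(normal = 75,
                                                  unstable_left = 25,
                                                  unstable_right = 25,
                                                  supination = 25,
                                                  pronation = 25))
segments <- segment_cohort(cohort, scheme = "stride")
features <- build_feature_table(segments, cohort)   # 172 retained columns
report <- run_loso(features, classifier_spec("svm", seed = 2))
report
```

Sensor-combination ablation, component sweeps and segmentation sweeps are
one call each — `run_sensor_ablation()`, `run_pc_sweep()`,
`run_segmentation_sweep()` — and `render_report()` writes the grids,
per-fold metrics, stored confusion matrices with error-rate rows, t-test
tables and explained-variance curves as CSV.

On default synthetic cohorts the qualitative structure a practitioner
expects is reproduced and is asserted by the test suite: multi-sensor
combinations match or beat their constituent single sensors; stride
segments (the longest scheme) classify at least as well as double-limb
support (the shortest); accuracy collapses to the majority-class share when
labels are permuted; and near-noiseless cohorts are classified almost
perfectly. The package makes no claim that synthetic accuracies transfer to
any real cohort.

## Known limitations

* The simulator's five classes are cleanly parameterized; real mimicked
  abnormal gaits are far noisier and participant-dependent, so synthetic
  accuracies sit near the ceiling in a way real data does not.
* Event detection is pressure-only by design; recordings without pressure
  channels cannot be segmented (inertial-only event detection is out of
  scope).
* In idealized gait the reference foot's swing and the opposite foot's
  single-limb support are the same interval, so their mean lengths tie
  rather than ordering strictly.
* The information-gain discretization (10 equal-width bins) is a pragmatic
  default; heavily skewed features would benefit from quantile binning,
  which is not implemented.
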