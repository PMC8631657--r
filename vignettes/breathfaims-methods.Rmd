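---
title: "Methods: breath volatolomics with TD-GC-FAIMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath volatolomics with TD-GC-FAIMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathfaims)
```

# The measurement and its data model

A TD-GC-FAIMS breath analysis desorbs volatile organic compounds (VOC)
from sorbent tubes into a GC column for retention-time separation, then
separates the emerging ions by differential mobility in an alternating
dispersion field (DF). Each analytical run yields, for each DF setting
(45, 55, 65 V), a positive- and a negative-ion intensity matrix over 512
compensation-field (CF) points spanning −6 to 6 V by 3460 time points,
with intensities in the 0–10 pA detector range. A run therefore carries
six matrices of ~1.77 million cells each.

The package models this as a `faims_run` (six matrices plus axes and
collection metadata) with a plain-text on-disk format: one directory per
run, a flat key–value metadata file, and six CSV matrices whose first
row is the time axis in seconds and first column the CF axis in volts.
Numbers are serialized with 6 significant digits; round-trips are exact
at that precision. The format is the package's own open dialect — the
vendor's binary export is undocumented and out of scope.

# Preprocessing

Per DF setting the pipeline applies three steps:

1. **Polarity combination.** The positive and negative planes are merged
   element-wise. The default rule is the maximum, which preserves the
   512 × 3460 shape and matches the idea of tracking the maximum ion
   peak intensity per resolved ion; a summation rule is available via
   `rule = "sum"`. Treating the published 512 CF points as per-polarity
   (combination is shape-preserving) is a deliberate reading of an
   ambiguous description.
2. **Blank subtraction** (optional). The paired room-air or air-filter
   blank, processed through the same polarity combination, is
   subtracted cell-wise; negatives are clamped to zero. Clamping is a
   package decision: downstream peak detection assumes non-negative
   intensities.
3. **Crop and collapse.** Rows with CF in the closed interval
   [−3, 3] V are retained (256 of 512 on the default axis; ties at
   ±3 V included) and the last 60 time points are dropped, then the
   CF-maximum at each retained time point forms the separation
   chromatogram (SC) of 3400 values. The crop is axis-driven rather
   than threshold-driven: a fixed window reproduces the published
   dimensions deterministically, and the fraction of discarded cells
   below the 0.0104 pA baseline ceiling is kept as a diagnostic
   (`baseline_fraction` attribute) rather than used as a criterion.

Cropping and collapsing commute (the tests assert this), so the order
is a presentation choice, not a numerical one.

# Molecular features

A molecular feature (MF) is a local SC maximum strictly above 0.5 pA —
a threshold above the 0.391 pA background-air ceiling, so background
fluctuations cannot produce features. Detection details that the
definition leaves open are fixed deterministically:

- plateau maxima resolve to the first plateau index;
- peaks closer than `min_separation` (default 5 time points, small
  relative to a 3400-point trace) are pruned keeping the more intense
  one, ties to the earlier index;
- the retention window extends outward from the peak to the first index
  that falls below the threshold or is a local minimum.

Features are coded by DF setting and retention rank (`"4501"` = first
peak at DF 45 V), quantified by peak maximum (pA) and trapezoidal peak
area on the physical time axis (pA·s), matched across samples by greedy
nearest-retention-time assignment within `rt_tolerance` (default 10
points — the cross-sample bracketing rule is a reconstruction, exposed
in the configuration), and averaged arithmetically across each
subject's technical replicates.

Group comparison uses a one-tailed **Welch** two-sample t-test (the
alternative: disease exceeds control). A paired test is not meaningful
between groups of unequal size, so the unpaired Welch form is used
throughout; zero-variance degenerate cases return p = 0.5 when the
means are equal. Percent difference is normalized by the control-group
mean, the natural reference. Per-feature AUC is the rank (Mann–Whitney)
statistic with ties counted one half; the tests verify it against
brute-force pair counting. Candidate selection requires >30 %
difference, p < 0.05 and AUC > 0.7, optionally with strictly increasing
stage means (stages 0→3).

# The MF score

The score is a logistic regression on the selected features — by
default the single best-AUC stage-trending feature, matching the
univariate reading of the original design; any feature set can be
passed. The fit is maximum likelihood via BFGS on standardized
features with an optional L2 penalty on the slopes (`ridge`, default
0): near-separable small cohorts push the unpenalized optimum toward
infinite slopes, and a weak penalty guarantees a finite optimum when
that matters. The unpenalized path is verified against `stats::glm`,
and parameter recovery at n = 500 (slopes within 15 % of a known
generative model) is part of the acceptance suite. ROC curves are
empirical step curves from (0, 0) to (1, 1) with trapezoidal AUC
(identical to the rank AUC); the default operating cutoff of 0.45 is a
configuration constant, not a fitted quantity.

# Classifiers

Full SC vectors — the three DF chromatograms concatenated (3 × 3400 by
default; single-DF mode via `df_settings`) — feed four algorithms, the
ones with reported results in this line of work, implemented behind one
registry:

- **RUSBT** (random under-sampling boosted trees): AdaBoost.M1 where
  each round trains an `rpart` tree (depth ≤ 3) on a class-balanced
  undersample drawn with the current boosting weights; rounds stop if
  the weighted error reaches 0.5. Scores are normalized weighted-vote
  margins. No installed package provides RUSBoost, so it is implemented
  here.
- **SKNN** (subspace k-NN): 30 k-NN learners (`class::knn`, k = 3),
  each on a random feature subspace of size ⌈√p⌉, averaged vote
  fractions. Also implemented in-package for the same reason.
- **GNB**: `e1071::naiveBayes` with a floor (10⁻³) on the per-class
  standard deviations, since zero-variance features otherwise produce
  degenerate densities.
- **GSVM**: `e1071::svm` with an RBF kernel of "medium" scale √p
  (γ = 1/(2p)), on the raw pA scale — baseline time points then
  contribute essentially nothing to kernel distances, which is what a
  chromatogram similarity should reflect — with inverse class weights
  so the 0.5 score cutoff stays meaningful on imbalanced cohorts
  (disease : control ≈ 3 : 1 in the study design).

Training uses a stage-stratified random split of 6 subjects per stage
(24 training subjects on the study-shaped cohort; the remaining 26
validate), stratified seeded 5-fold cross-validation, and strict
CV-AUC > 0.7 model selection. Validation asserts subject-level
disjointness (a leakage error otherwise) and reports both per-sample
and per-subject metrics, since multiple tubes per patient make the two
differ. The blank-subtraction ablation retrains the same specification
under the three modes (none / air filter / room air) on one shared
split.

The **tandem** cascade applies a stage-3 stager only to
detector-positive samples, so its any-disease sensitivity equals the
detector's by construction; outputs are no disease / compensated /
decompensated.

# Variability via embeddings

Each combined DF matrix is pooled row-major into a fixed-length
block-mean embedding (default 2048 values, the width of a typical CNN
feature layer). This deterministic embedding replaces a pretrained
CNN feature extractor: it preserves the analysis structure —
fixed-length vectors compared by mean pairwise Euclidean distance
(EMD) — without trained weights, and a plug-in function of the same
signature can substitute any other embedding. Distances are computed
per DF plane and averaged across the three planes. The report gives
within-technical, within-day and between-subject EMD and flags whether
between-subject variability exceeds both within-subject levels — the
qualitative ordering that justifies classification across subjects.
The printed EMD magnitudes of CNN activations are not comparable to
block-mean magnitudes and are not a target.

# The synthetic cohort generator

Because no raw cohort data are deposited, the generator is a
first-class, tested module that defines the study conditions:

- grid 512 CF × 3460 time points, 0–10 pA, run time 2164.1 s;
- stage counts 11/14/15/10 (n = 50), four technical replicate tubes;
- baseline noise: i.i.d. half-normal per cell, sd 0.002 pA, capped at
  the 0.0104 pA baseline ceiling (the cap keeps the noiseless-baseline
  invariant exact rather than probabilistic);
- background peaks ≤ 0.391 pA (below the MF threshold by design);
- run-time jitter: one uniform draw in ±0.18 % per sample, applied as a
  multiplicative stretch of retention centers and of the run duration;
- between-subject lognormal amplitude variation (sd 0.3) and day-to-day
  lognormal variation (sd 0.15, in the spirit of the ~15 % day-to-day
  CV such protocols report);
- marker peaks amplified per stage, default multipliers
  (1, 1.3, 1.6, 2) — the study reports no quantitative VOC effect
  sizes, so these are free parameters chosen to give a realistic,
  non-trivial classification problem, not estimates of real effects;
- each breath run has paired room-air and air-filter blanks sharing its
  environmental amplitudes and jitter, so noiseless blank subtraction
  removes environmental signal exactly (a tested conservation
  invariant). The two blank types are statistically identical by
  default, so the blank-mode ablation is a near no-op unless the user
  plants environmental structure.

Peaks are separable 2-D Gaussians in (CF, time) — the simplest shape
consistent with depicted FAIMS peaks and sufficient for ground-truth
recovery testing. The generator does **not** emulate humidity-induced
signal degradation, sorbent-storage artifacts, co-elution-induced peak
superposition, baseline drift, or retention-time warping beyond the
global stretch; passing tests therefore demonstrate correctness of the
computational pipeline on idealized signals, not robustness to those
real-world artifacts.

Stage-3 subjects can be flagged as non-cirrhotic portal hypertension
(`n_ncph`, default 0) to emulate the handful of such participants;
task labelling can include or exclude them.

# Problem sizes and numerical choices

Cohort-level tests and the acceptance script run the generator on a
reduced 32 × 200 grid (the signal model is scale-free; peak positions
are fractions of the time axis), with single full-size 512 × 3460 runs
reserved for the shape-contract checks. The analysis drivers use the
study-shaped cohort (50 subjects, 4 replicates) on the reduced grid.
Separable-cohort checks plant stage multipliers (1, 4, 4, 7) with
between-subject sd 0.05 so the classes are cleanly separated; the
label-permutation check retrains on 20 shuffled label vectors and
expects a mean validation AUC near 0.5.

Other numerical conventions: time indices are 0-based internally with
physical axes carried for reporting; feature matrices use NA for absent
features (replicate averaging is NA-aware); the logistic likelihood
uses a numerically stable softplus; RUSBoost caps the weighted error at
10⁻¹⁰ before computing the round weight.

# Known limitations

- The cross-sample MF matching rule is a reconstruction; alternative
  bracketing rules could merge or split features near the tolerance.
- The one-tailed test direction is fixed globally (disease > control),
  not chosen per feature.
- The classifier registry is the four reported algorithms; it is
  extensible but no hyperparameter search is provided.
- Printed clinical operating points from the original cohort (MF-score
  AUC, classifier sensitivity/specificity, EMD magnitudes) depend on
  undeposited patient data and are outside what synthetic cohorts can
  or should reproduce.
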