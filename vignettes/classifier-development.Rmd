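---
title: "Developing a multi-cancer early-detection classifier from EV-protein panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a multi-cancer early-detection classifier from EV-protein panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmced)
```

## The problem

Multi-cancer early detection (MCED) from blood asks a classifier to flag
stage I--II cancers at a *very* low false-positive rate: at population
scale, every percentage point of lost specificity swamps the screening
programme with work-ups of healthy people. `evmced` implements, as a
reusable and fully tested pipeline, the classifier-development procedure
used for plasma extracellular-vesicle (EV) protein panels in a
case--control setting: pancreatic, ovarian and bladder cancer cases
against cancer-free controls, with a marker panel quantified by
multiplex immunoassay and an age covariate.

The pipeline has five stages, each an exported function:

1. **Preprocessing** (`filter_markers()`, `impute_and_log2()`) --
   limit-of-detection (LOD) aware cleaning.
2. **Marker selection** (`rfe_select()`) -- recursive feature elimination
   with repeated stratified cross-validation, maximizing the partial AUC
   over a high-specificity band.
3. **Resampling** (`resample_fit()`) -- repeated stratified 2/3--1/3
   train/test splits of an unpenalized logistic classifier, with
   per-subject averaging of held-out scores.
4. **Threshold calibration** -- a per-split threshold at the target
   specificity, averaged into a single operating point.
5. **Evaluation** (`evaluate()`) -- cohort and sub-cohort sensitivity and
   specificity with Wilson intervals, AUC with a bias-corrected
   bootstrap interval, and standardized-coefficient importance.

`run_pipeline()` chains them and writes every intermediate artifact as
plain CSV/JSON.

## Preprocessing model

Immunoassay panels report left-censored concentrations: values below a
marker's LOD are unreliable or absent. Three rules, applied in order:

* **Prevalence filter.** A marker is kept only if the fraction of its
  values that are missing *or strictly below* its LOD, pooled over cases
  and controls, is below 50% (`marker_missing_max_frac`). Pooling over
  the full cohort is the simplest reading of the protocol; values exactly
  at the LOD count as observed.
* **LOD imputation.** Remaining missing/below-LOD cells are set to the
  marker's LOD. This is deliberate: under a >99%-specificity objective,
  imputing at the detection floor is conservative and keeps the censored
  mass at a single point rather than inventing spread below it.
* **log2 transform.** Marker concentrations span orders of magnitude
  ("wide" distributions); log2 makes shifts multiplicative and roughly
  variance-stabilizes a log-normal marker. Age is appended untransformed
  -- it is a covariate, not an assay value.

Replicate measurement rows for a subject are averaged (arithmetic mean of
non-missing replicates) *before* the LOD comparison; the protocol does
not state the reduction, and the mean is the simplest symmetric choice.

## Why partial AUC drives selection

Marker selection maximizes the *unnormalized* partial AUC (pAUC) over
specificities 0.75--1.00 -- the trapezoidal area of the ROC curve
restricted to FPR $\le$ 0.25, with linear interpolation at the band
edges (the pROC convention). Its maximum is the band width 0.25; the
chance diagonal scores $0.25^2/2 = 0.03125$. Optimizing pAUC rather than
full AUC tilts selection toward markers that help in the low-FPR corner
where an MCED test actually operates. Whether to normalize the pAUC is a
display choice only: selection compares pAUCs of candidate subsets, and
the affine McClish rescaling preserves the argmax.

`rfe_select()` runs true stepwise backwards elimination: within each of
`rfe_reps` repetitions (default 100) of a class-stratified K-fold
partition (default K = 5), the model is fit on K-1 folds, markers are
ranked by $|\beta_j \cdot \mathrm{sd}_j|$ (the absolute standardized
coefficient on the training folds), the weakest is dropped, and the model
is *refit* -- down to one marker, scoring every subset size on the
held-out fold. The subset size with the best mean held-out pAUC wins
(ties to the smaller size); the final panel is the top markers by mean
elimination-order rank across all repetitions and folds (rank 1 = last
survivor; ties alphabetical), the same aggregate-rank convention caret
uses for its RFE variable lists. Age is present in every candidate model
and exempt from elimination; the protocol is ambiguous on this point, and
always-include is the choice that keeps the age adjustment stable across
subset sizes.

## The classifier and its importance measure

The classifier is plain maximum-likelihood logistic regression -- no
penalty, because the standardized-coefficient importance
$\mathrm{mean}_t\,|\beta_j^{(t)}\,\mathrm{sd}_j^{(t)}|$ (rescaled so the
maximum is 100) would be distorted by shrinkage. Fitting uses IRLS
(epsilon 1e-8, at most 100 iterations). Near-separable training splits
are expected in a >99%-specificity regime; rather than abort, a fit with
any training linear predictor beyond ±30 is kept, flagged
`converged = FALSE`, and linear predictors are capped at ±30 at
prediction time so probabilities stay inside (0, 1). Constant features
are dropped with a warning and report coefficient 0, keeping fits over a
common feature set comparable.

## Resampling and threshold calibration

With ~323 subjects, a single train/test split is fragile. The pipeline
draws `resamples` (default 100) independent partitions, stratified by
cancer type (controls are their own stratum): each stratum contributes
`round(n_s * 2/3)` subjects to training -- 123 of 184 controls, so every
test set holds exactly 61 controls. Per split $t$ a threshold $\tau_t$ is
calibrated on the *test-set control* scores as the smallest threshold
whose false-positive fraction is at most $1 - 0.99$; with 61 controls
that is the maximum control score, i.e. all 61 are called negative
(strict `score > threshold` rule; ties at the threshold are negative).

Each subject's held-out probabilities are averaged over the splits in
which they were tested (the "average fit", on the probability scale --
the natural scale for averaging fits of a probability model), the
per-split thresholds are averaged into $\bar\tau$, and the final call is
`mean score > tau_bar`. One subtlety worth knowing: per-split calls are
perfectly specific by construction, but the *averaged* threshold can
flip a control whose score sets the per-split threshold whenever it is
tested -- its mean score can exceed the mean of thresholds. This is not a
defect; it is why a 99%-calibrated procedure reports, e.g., 183/184
(99.5%) rather than 184/184 specificity on the full cohort. Under
quasi-separation, where probability scales differ wildly between splits,
more than one saturated control can flip.

At tiny `resamples` a subject may never be tested; such subjects get no
call and are excluded from metrics with a warning.

## Interval estimates

* **Sensitivity/specificity:** two-sided Wilson score intervals (no
  continuity correction), $z = 1.959964$ at the 95% level. The Wilson
  interval inverts the normal score test and behaves well at proportions
  near 0 and 1, which is exactly where a high-specificity test lives;
  the upper bound is exactly 1 when $k = n$.
* **AUC:** stratified bootstrap (cases and controls resampled separately,
  preserving counts -- avoiding degenerate single-class replicates),
  B = 2000 replicates, bias-corrected (BC) percentile interval with
  $z_0 = \Phi^{-1}(\#\{\mathrm{AUC}^* < \mathrm{AUC}\}/B)$. No
  acceleration term (BC, not BCa). A degenerate bootstrap distribution
  collapses to a point interval with a warning; a boundary $z_0$ is kept
  finite by clamping the fraction to $[1/(B{+}1), B/(B{+}1)]$.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable without any data
download. It draws marker panels as $2^X$ with $X$ multivariate normal
on the log2 scale: per-marker baseline mean 6 and SD 1.5 (wide on the
natural scale), equicorrelated blocks (size 6, $\rho = 0.3$) standing in
for the assay-panel correlation structure, per-cancer mean shifts on
that cancer's informative markers, LODs placed at a stated quantile of
the control marginal (so censoring fractions are controllable by
construction), missing-at-random masking (2%), and ages from clipped
normals with control median near 57 (range 40--71) and case median near
60 (range 21--76).

`study_like_spec()` freezes the study-shaped preset: 184 controls,
47/44/48 pancreatic/ovarian/bladder cases (323 subjects), 42 markers of
which 13 are informative with overlapping per-cancer subsets (8 each),
published stage counts (pancreatic 22 I / 25 II; ovarian 39 I / 5 II
with 26 stage IA and 22 serous; bladder 27 I / 21 II), all-female
ovarian cases, and 8 markers censored at the 70% control quantile so the
prevalence filter drops them (34 of 42 retained). The per-cancer effect
sizes -- log2 shifts of 4.0 (pancreatic), 2.6 (ovarian) and 1.8
(bladder) -- were chosen once so that the synthetic cohort reproduces
the discriminability regime the procedure is designed for: overall AUC
around 0.95, strong pancreatic and moderate ovarian sensitivity, weak
bladder sensitivity at the calibrated threshold. They are structural
realism, not a fit to any measured dataset.

What the generator does *not* emulate: real per-marker concentration
scales and LODs, skewness beyond log-normality, batch/plate effects,
age--marker interactions, and assay-specific censoring mechanisms
(censoring here is exactly at a marginal quantile). Tests passing on
synthetic cohorts therefore validate the *procedure* -- selection,
calibration, interval construction -- not the clinical performance of
any real panel.

## Numerical and degenerate-input choices

* ROC curves group tied scores into a single step; thresholds are
  midpoints of adjacent distinct scores with ±Inf endpoints. AUC is the
  trapezoidal area and equals the tie-corrected Mann--Whitney
  probability to machine precision.
* `threshold_at_specificity()` computes
  `floor(n * (1 - target) + 1e-9)` allowed false positives; the 1e-9
  guards the floating-point representation of expressions like
  `200 * 0.01`.
* Elimination ties (equal importance) drop the alphabetically first
  marker; selected-size ties take the smaller panel -- both make runs
  reproducible bit for bit.
* All Monte-Carlo stages draw per-repetition substreams from one root
  seed, so repetition results do not depend on execution order, and
  `compare_feature_sets()` runs two panels under literally identical
  split sequences.
* Zero-variance markers: dropped (with warning) inside fits; `NA`
  correlations in `correlation_matrix()`.

## Problem sizes used in the test suite

The suite validates statistical properties at sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while
keeping a single-CPU run comfortable: the AUC/pAUC oracles at 1000 and
20 random instances, bootstrap coverage at 400 simulation replicates
with B = 1000 (binomial MC error ~1.1% against a 92--98% acceptance
band), marker-recovery at 11 generator seeds with 20 RFE repetitions,
and one full default-settings end-to-end run. The acceptance script
(`scripts/acceptance.R`) always runs the complete pipeline at default
settings (100 RFE repetitions, 100 resamples, B = 2000).

## Known limitations

* Selection happens once, before the 100 resamples (the protocol's
  ordering); the resampled performance therefore carries the optimism of
  the selection step. A nested selection-inside-resampling design is out
  of scope.
* The LOD-imputation point mass can make a heavily censored marker look
  artificially stable; the prevalence filter is the only guard.
* No multiclass tissue-of-origin prediction -- the classifier detects
  cancer presence only.
* `wilson_ci()` treats per-subject calls as independent Bernoulli
  trials; the averaging over shared splits induces a small dependence
  the interval ignores (as does the reference protocol).
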