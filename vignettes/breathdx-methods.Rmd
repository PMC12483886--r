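---
title: "Methods: breath VOC screening and diagnostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath VOC screening and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`breathdx` implements a complete diagnostic-modelling workflow for exhaled
breath volatile organic compounds (VOCs) measured by thermal-desorption
GC-MS, aimed at separating malignant from benign thoracic lesions. The
input is the pair of matrices produced by upstream peak
detection/alignment software: a samples x compounds peak-area matrix and a
same-shape signal-to-noise (SNR) matrix, plus a per-sample sheet with
diagnosis, subtype, AJCC stage, pre-/post-operative timepoint, and optional
serum tumor markers. Everything downstream of peak alignment is covered:
quality control, normalization, biomarker screening, classifier
construction, and evaluation statistics including post-operative
monitoring.

Because no public breath dataset accompanies this workflow, the package
ships a synthetic cohort generator (`generate_cohort()`) that emulates the
statistical structure such a study produces, with ground truth recorded, so
the entire pipeline is testable end to end.

## Quality control and normalization

A measurement is **valid** when its SNR strictly exceeds 10; an SNR of
exactly 10 is invalid, as is a missing SNR. QC then proceeds in a fixed,
documented order:

1. *Sample filter.* Each sample's response rate is the fraction of valid
   measurements across **all** compounds; samples below 0.80 are dropped
   (0.80 exactly is retained).
2. *Compound filter.* Compound response rates are computed over the
   **retained** samples only; compounds below 0.50 are dropped (0.50
   exactly is retained).

Computing compound rates after the sample filter matters: a compound can be
rescued by the removal of a globally poor sample. The reverse order is a
one-line change but is not the default.

Normalization of the filtered ("valid") area matrix is a four-step
pipeline in fixed order:

(a) **Half-minimum imputation**: each invalid entry is replaced by half the
    minimum valid area of its compound — the standard metabolomics
    treatment of measurements below the effective detection limit;
(b) **log10 transform**, addressing the multiplicative (heteroscedastic)
    error structure of peak areas;
(c) **per-sample median centering**, removing sample-loading and
    instrument-response offsets (a per-sample constant on the log scale);
    a total-signal variant (`method = "total"`) is available;
(d) **per-compound z-scaling**, with mean and standard deviation estimated
    on a designated reference subset only — the training samples — and
    applied to all samples. Learning scaling parameters on the training
    split keeps the held-out evaluation honest; a compound with zero
    variance on the reference gets sd = 1 and a recorded warning.

Step (c) makes the output invariant to per-sample multiplicative scaling of
raw areas, which is the stated purpose of the loading correction; a unit
test verifies the invariance exactly.

## Dual-criteria biomarker screening

Each compound is tested for a location difference between classes with the
two-sided Wilcoxon rank-sum test (exact by enumeration when the smaller
group has at most 8 observations and there are no ties; otherwise the
normal approximation with tie-corrected variance and continuity
correction). In parallel, an OPLS-DA model with one predictive component
and (by default) one orthogonal component is fitted to the full matrix, and
variable importance in projection (VIP) scores are computed on the
predictive component only — the standard OPLS-DA convention, stated
explicitly because VIP variants differ. With a single predictive component
the score reduces to `sqrt(p) * |w_j| / ||w||`, so `sum(VIP^2) = p` holds
identically; this is asserted on every fit in the test suite.

A compound is a **candidate biomarker** iff `p < 0.05` and `VIP > 1`, both
strict, and it is not on the user-supplied exclusion list. The exclusion
list models the manual curation step of real studies (removing drug
metabolites, environmental contaminants and annotation failures), which is
inherently non-algorithmic; the package treats it as data, not code.

The OPLS-DA implementation follows the orthogonal-projection scheme for a
single response: the class is coded ±1 and centered; for each orthogonal
component the part of the predictive loading orthogonal to the weight
vector is extracted, its score removed from X, and the predictive weight
refitted; with zero orthogonal components the model is exactly
one-component PLS-DA (verified against an independent PLS implementation in
the tests).

## Partition, feature selection, model, threshold

- **Split.** Pre-operative samples are randomly partitioned, stratified on
  class, into a discovery set of `floor(0.60 n)` samples and a testing set
  of the remainder; per-class allocations use largest-remainder rounding.
  For a 132-sample cohort this yields 79/53. (The flooring convention is a
  deliberate choice; the alternative 80/52 rounding appears in some
  descriptions of such designs.)
- **Ranking.** Candidates are ranked by univariate training AUC, with `a`
  and `1 - a` treated symmetrically; ties break by smaller screening
  p-value, then compound id.
- **Forward selection.** Starting from the top-ranked candidate, features
  are added one at a time. After each addition the regularized logistic
  model is assessed by 5-fold stratified cross-validation (mean out-of-fold
  AUC, mild ridge penalty of 0.01 during selection). Selection stops when
  the improvement over the running best is at most `delta = 0.005` for
  `patience = 2` consecutive additions; the chosen size is the argmax of
  the recorded trace (smallest k on ties). "No further significant
  improvement" is not a numeric rule in the underlying protocol; delta and
  patience are the package's quantification and both are exposed.
- **Hyperparameters.** An exhaustive grid — penalty {L1, L2}, strength
  {0.01, 0.1, 1, 10}, class weights {uniform, inverse-frequency}, iteration
  cap {100, 1000} — is scored by the same stratified-CV AUC; ties resolve
  to the earliest grid row. The logistic fits are elastic-net binomial
  models at a single fixed penalty (glmnet), without internal
  standardization since compounds are already z-scaled.
- **Threshold.** The decision cutoff maximizes the Youden index
  J = sensitivity + specificity − 1 over candidate thresholds placed at
  midpoints between consecutive distinct training scores (with ±Inf
  sentinels); ties prefer higher specificity, then the lower threshold.
  The classification rule is `score >= threshold` ⇒ malignant. The
  published cutoffs of such workflows (e.g. 0.64) are data-derived
  realizations of this rule, not constants of the method.

A structural guard test asserts that the whole training path — screening,
ranking, selection, tuning, fitting, thresholding — reads only
discovery-set rows: corrupting every held-out row leaves the fitted model
bit-identical.

## Evaluation statistics

- **AUC** is the pairwise probability of correct ordering (ties count
  half), computed via midranks and verified against brute-force pair
  enumeration.
- **Binomial confidence intervals** use the Wilson score interval.
  The choice is forced by reverse-engineering published subgroup intervals
  of this study design: Wilson reproduces all printed pairs after rounding
  — for example 3/3 → 44–100%, 15/21 → 50–86%, 41/47 → 75–94% — while
  Clopper–Pearson does not (3/3 has lower bound 29%). Clopper–Pearson
  remains available by flag. The F1 interval treats F1 as the proportion
  `2TP / (2TP + FP + FN)`; the AUC interval uses the DeLong variance with
  a normal reference.
- **DeLong test** for two correlated AUCs via placement-value covariance;
  degenerate cases are defined (identical scores give p = 1; zero variance
  with unequal AUCs is an error).
- **McNemar's test** on paired correctness indicators: exact two-sided
  binomial p when the discordant count is at most 25, chi-square with
  continuity correction above.
- **Serum panel.** A subject is panel-positive when any available marker
  exceeds its normal-range upper limit strictly (CA125 35 KU/L, ProGRP 46
  ng/L, CEA 5 µg/L, CYFRA21-1 3 ng/L); subjects with all markers missing
  are excluded, not counted negative. Model-versus-panel sensitivity on
  malignant samples is compared with McNemar's test.
- **Monitoring.** Per-subject pre/post-operative score changes are tested
  with a paired two-sided t-test (a signed-rank alternative is available,
  since predicted probabilities are bounded).

## The synthetic cohort generator

`generate_cohort()` draws, per compound, a baseline log10 area from
U(4, 7) and a within-group standard deviation from U(0.3, 0.6) (log10
units). A sample's log10 area adds a per-sample loading offset
(N(0, 0.15)), a subject-level deviation shared between a subject's pre- and
post-operative samples (half the compound variance), and an independent
residual. A planted subset of compounds is shifted upward by `effect_size`
(log10 units) in malignant pre-operative samples; post-operative malignant
samples retain `1 - postop_effect_removal` of the shift (default removal
0.8), so surgery attenuates but does not erase the signature. SNR is
generated as `snr_scale × area / noise` with per-entry log-normal noise
around the compound baseline, making low-abundance measurements drift
below the SNR = 10 validity gate; each compound additionally invalidates
entries at its own rate drawn from `missing_rate_range`. Serum markers are
generated as exceedances of the printed normal ranges with per-marker
sensitivities (defaults 0.061/0.121/0.152/0.242 for
CA125/ProGRP/CEA/CYFRA21-1) in malignant subjects and a 2% false-positive
rate in benign subjects.

Cohort defaults mirror the emulated study: 97 malignant (lung cancer :
thymoma : esophageal cancer ≈ 77:13:7, staged mostly 0–II) versus 35
benign subjects, 200 compounds, 13 planted markers, and a 55% paired
post-operative sampling fraction.

**Effect-size calibration.** `effect_size_for_auc(a)` converts a target
per-compound univariate AUC into a log10 shift via
`qnorm(a) * sqrt(2) * sd`. The default effect is calibrated to a
per-compound AUC of 0.6, matching the per-VOC discriminant values printed
for this study design (reported AUC range 0.58–0.65). Two caveats are
documented deliberately. First, the published per-VOC table is internally
inconsistent: its p-value column (0.007–0.049 at 59 vs 20 samples) implies
univariate AUCs of 0.65–0.70, which cannot arise from the same rank-sum
statistics as the printed AUC column. Second, a per-compound AUC of 0.6
corresponds to a rank-sum power of roughly 0.3 at the discovery-set size,
so a 13-compound planted signature is *not* mostly recoverable by
screening at that effect size — published marker tables in which every
selected compound is significant are post-selection views, not recovery
rates. The acceptance suite runs at this documented calibration and
records the resulting recovery honestly; the strong-effect regime
(`effect_size = 1.0`), where screening recovery, the post-surgery score
drop and the serum-panel comparison all reproduce the expected qualitative
pattern, is exercised in separate tests.

What the generator does **not** emulate: inter-compound correlation
(a shared disease-burden factor), retention-time drift, batch effects,
chromatographic artifacts, and diet/smoking covariates. Passing tests on
this generator therefore demonstrate correctness of the statistical
machinery under the stated model, not clinical validity on real breath
data. In particular, because planted compounds are independent, the
cross-validated AUC gains from successive features decay faster than a
correlated-marker panel would show.

**A monitoring caveat.** The pre/post analysis scores all paired subjects,
including discovery-set subjects whose pre-operative samples shaped feature
selection — matching how such studies analyze their monitoring cohorts.
This induces a regression-to-selection artifact: benign training subjects'
pre-operative values are conditioned by selection to look "benign-low", so
their post-operative scores drift upward spuriously. The artifact is
negligible when selected features carry strong real signal and grows as
the model degenerates toward noise; restricting monitoring to held-out
subjects removes it at the cost of sample size.

## Numerical and degenerate-case conventions

- SNR exactly 10 is invalid; response rates exactly at 0.80/0.50 are
  retained; screening inequalities (p < 0.05, VIP > 1) are strict.
- Rank-sum on two identical multisets returns p = 1 (no evidence), not an
  error.
- All scores equal: the Youden search returns a sentinel with a warning;
  the final-model fitter falls back to a 0.5 threshold.
- Zero DeLong variance with zero AUC difference gives p = 1; with a
  non-zero difference it is an error (degenerate pairing).
- Stratified folds are reduced (with a warning) when the smaller class has
  fewer members than the requested folds.
- A single master seed fans out to fixed per-stage seeds; identical
  configurations reproduce every output bit for bit, and cohort files
  round-trip losslessly through the TSV/CSV/JSON writers.

## Problem sizes used in the validation suite

The test suite exercises cohorts of roughly 45–132 subjects and 60–600
compounds, Monte-Carlo calibration with 500 replicates per test, a
2000-resample bootstrap cross-check of the DeLong test, and ten-seed
replications of the screening-recovery and end-to-end experiments; these
sizes make the full suite run in a few minutes while keeping every
Monte-Carlo band wide enough for its replicate count.
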