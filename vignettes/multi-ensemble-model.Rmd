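---
title: "An under-sampling ensemble for occult ovarian-cancer risk at RRSO: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An under-sampling ensemble for occult ovarian-cancer risk at RRSO: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsorisk)
```

## The problem

Women carrying pathogenic BRCA1/BRCA2 variants are offered risk-reducing
salpingo-oophorectomy (RRSO). In a small fraction of them — about 7.6% in the
cohort this package models (184 patients, 14 positives: 6 serous tubal
intraepithelial carcinomas and 8 early invasive carcinomas) — the resected
tissue already harbours an occult adnexal tumor. Predicting that risk from 20
routinely collected clinical variables (age, BMI, menarche age, BRCA status,
CA-125, menopausal status, reproductive history, endometriosis, prior surgery
and breast cancer, and family history of breast/ovarian cancer) is a heavily
imbalanced binary classification problem: a classifier trained naively on such
data learns to call everything negative.

`rrsorisk` implements a multi-ensemble of random under-sampling models for
this setting, together with everything the analysis needs around it:
a synthetic-cohort generator reproducing the published marginal
distributions, proximity imputation, standardization, leave-one-out (LOO)
evaluation with Youden-index thresholding, feature-frequency summaries and
exact additive Shapley explanations.

## The model

For each LOO fold (one patient held out), the remaining patients form the
training pool, and three families of under-sampled training sets are drawn —
class ratios 1:1, 1:2 and 1:3 (rare : abundant) — with `n_models` (default
100) sets per ratio. Every set contains *all* available rare-class patients
and exactly `ratio × N_rare` abundant patients drawn uniformly without
replacement (sets may overlap; draws are independent across sets). Each set
trains the shared backbone:

1. **Feature selection.** A 100-tree Random Forest scores every feature by its
   Gini-impurity decrease, normalized to sum 1; a feature is retained when its
   importance is *strictly greater* than the median importance. With 20
   features and distinct importances this keeps exactly 10. If the strict rule
   empties the mask (degenerate all-equal importances), the backbone falls
   back to all features and warns.
2. **Classification.** A soft-margin linear SVM (C = 1) on the retained
   features. Because a raw SVM margin is unbounded, the margin is mapped to a
   [0,1] score by Platt-style sigmoid calibration fitted on the training
   margins with the regularized targets `(n+ + 1)/(n+ + 2)` and `1/(n- + 2)`
   (Newton iteration); these targets keep the fit finite on separable data.
   The score is strictly increasing in the margin and `score > 0.5` predicts
   the rare class.

Per ratio, the `n_models` sub-model votes are combined by **majority voting**:
the winning class is the modal class, and the aggregated ratio score is the
*maximum* score among rare-voting sub-models when the rare class wins, or the
*minimum* score among abundant-voting sub-models when the abundant class wins.
A 50/50 tie (possible with an even `n_models`) resolves to the rare class —
the screening-oriented choice, maximizing sensitivity — and is counted in the
run log. The final patient score is the **soft vote**: the arithmetic mean of
the three ratio scores.

## Evaluation

`roc_auc()` builds the ROC curve over the midpoints between consecutive
distinct scores (plus sentinels), classifies by strict `score > threshold`,
and integrates by trapezoid; this equals the rank/concordance statistic
`P(score_rare > score_abundant) + 0.5 P(equal)` under any tie pattern, which
the tests verify against an enumeration oracle and an independent ROC
implementation. `youden_threshold()` maximizes J = sensitivity +
specificity − 1, breaking ties toward the lower threshold (favoring
sensitivity); a sentinel winner is mapped to a finite threshold with the same
confusion table, with a warning when the curve is degenerate (max J = 0).
`confusion_metrics()` reports accuracy, sensitivity, specificity and
`G-mean = sqrt(sensitivity × specificity)` — the geometric mean, the
balance-sensitive summary appropriate for imbalanced data.

The threshold is chosen on the same LOO scores being reported, replicating the
published protocol. This is optimistic: the threshold sees the evaluation
scores. A deployment would need to fix the threshold on independent data.

`original_model_baseline()` is the comparison model: the identical backbone
trained once per fold on *all* remaining patients, no resampling, no voting.
On imbalanced data its LOO AUC is expected to fall at or below chance — the
held-out rare patient faces a model trained with one fewer rare example, a
known small-class LOO artifact that the under-sampling ensemble avoids by
balancing every training set.

## Explanations

Every sub-model is linear in the selected features, so Shapley values under
feature independence have the exact closed form
`phi_i = w_i (x_i − mean(background_i))` in margin space, where the background
is the sub-model's training set; the tests confirm this against full coalition
enumeration. Contributions are reported in score space by rescaling with the
secant slope of the calibration curve between the background-mean margin and
the evaluation margin, so the additivity identity
`base_value + sum(phi) = score` holds exactly for the reported [0,1] score;
margin-space values are also kept for audit. The **base value** is the
calibrated score at the background-mean margin — the expected prediction when
no feature value is known. (Defining it instead as the average of training
scores would break both additivity and the identity "a patient at the
background mean scores the base value", because the calibration is nonlinear.)

Per ratio, the explained sub-model is the one whose score the majority vote
propagated (the max/min model), so the explained score equals the ratio score
exactly. The ensemble explanation averages the three ratio explanations
feature-wise (base values and scores average too, consistent with the soft
vote); a feature pushing in opposite directions across ratios nets out near
zero. Averaging over all sub-models of a ratio instead of the vote-selected
one is available behind `method = "mean-over-models"`; it treats all 100
sub-models equally but no longer matches the propagated score, so it is not
the default.

## The synthetic generator

The original cohort is not public. `default_config()` therefore encodes the
published cohort description exactly: n = 184, 14 rare (6 STIC + 8 invasive),
per-feature marginals and absolute missing-value counts. Continuous features
are drawn from a piecewise-linear inverse CDF through the published
(q1, median, q3) with exponential tails of scale IQR/2 beyond the quartiles,
clipped at clinical plausibility bounds (Age ≥ 18, BMI ≥ 14, menarche ≥ 8,
CA-125 ≥ 0) — this reproduces the published quartiles without asserting a
parametric family. Binary features are Bernoulli at the observed Yes fraction.
Count features are sampled on {0,…,4} with probabilities chosen once to match
the published median/quartiles: (0.15, 0.20, 0.45, 0.15, 0.05) for full-term
pregnancies (median 2, quartiles [1, 2]) and (0.60, 0.30, 0.08, 0.02, 0) for
the four relative-count features (median 0, quartiles [0, 1]).

Class counts and planted NA counts are exact for every seed, not expected
values; missingness is uniform over patients and never touches the outcome.
Optional effects plant signal *before* missingness (so imputation sees
realistic attenuation): a continuous effect shifts the rare-class mean by
`effect × IQR`, a binary effect shifts the rare-class log-odds by `effect`,
and a count effect tilts the category probabilities by `exp(effect × k)`.

What the generator deliberately does **not** emulate: inter-feature
correlation (only marginals are published, so features are independent — age
and menopausal status, for example, are clinically coupled but not here),
informative missingness, any real feature–outcome association beyond planted
effects, and any distributional difference between STIC and invasive subtypes
(the model treats a single rare class). Tests passing on these cohorts
therefore demonstrate pipeline correctness, imbalance handling and null
calibration — not clinical performance. The published headline metrics
(accuracy 83.2%, specificity 85.3%, sensitivity 57.1%, G-mean 69.8%, AUC
71.1%; per-ratio AUCs 68.3/59.5/65.7%; baseline AUC 35.8%) were obtained on
the private cohort and are quoted here as reference values only; they are not
reproducible without it.

## Preprocessing

Missing values are filled by a proximity rule: the donor for a patient is the
fully-observed patient minimizing the Euclidean distance computed over exactly
the features the recipient has observed; the recipient takes the donor's
values for all its missing features (one donor per recipient). Distances use
raw, unstandardized values — imputation precedes standardization in the
pipeline — which lets large-scale features (CA-125) dominate the metric; this
mirrors the published sequencing and is logged per imputation. Equidistant
donors break to the lowest row index, deterministically, and the tie is
recorded. Imputation is idempotent and never synthesizes values outside the
observed support.

Continuous features are then standardized to zero mean and unit *population*
variance. The default mode fits the scaler on the entire dataset before
cross-validation, as published; `standardize_mode = "train-only"` refits it
per fold on the training pool only, for a leakage-safe variant.

## Determinism and numerical choices

All randomness flows from one master seed through a positional hash:
`seed(fold, ratio, model) = hash(master, fold, ratio, model)` modulo
2^31 − 1. Any single sub-model is re-derivable in isolation, fold order is
irrelevant, and scoring a subset of folds (`loo_predict(..., folds = ...)`)
reproduces bit-identical scores to the corresponding folds of a full run.
Fixed conventions, each logged where it fires: Gini importances tied exactly
at the median are excluded (strict inequality); vote ties go to the rare
class; score ties at the decision threshold go to the abundant class (strict
`>`); equidistant donors go to the lowest row index. SVM solver tolerance is
1e-4 (tightened to 1e-9 inside the test probing permutation invariance, to
separate the property from the solver's order-dependent stopping point). The SVM margin is
re-oriented after fitting so that positive always means rare, because libsvm's
decision-value sign follows the order labels appear in the data.

Univariate screening uses the rank-sum test with tie-corrected normal
approximation (no continuity correction) for continuous and count features,
and Pearson's chi-square without continuity correction for binary features,
at raw p < 0.1 with no multiple-testing correction — the published rule. A
single-level feature gets p = 1 by convention; a table with expected counts
below 1 is flagged but still tested. At very small training sets the normal
approximation is anti-conservative relative to exact enumeration (for
{1,2,3} vs {4,5,6} it gives p ≈ 0.05 where exhaustive enumeration gives 0.1);
the approximation is the deliberate contract, since resampled training sets
are routinely tied and the exact null is impractical there.

## Simulation scales used by the test suite

The packaged tests exercise the published configuration's *structure* (300
sub-models per fold, exact 1:r ratios, leakage guards) via plan arithmetic,
and run the full pipeline at reduced scale chosen to keep the suite fast while
leaving the measured properties unchanged in expectation: ensembles of 3–10
sub-models per ratio, cohorts of 18–60 patients for signal-recovery checks,
and — for the null-calibration study — 50 default-size cohorts (n = 184) with
10 sub-models per ratio, scoring a stratified subset of LOO folds (all 14
rare patients plus 42 abundant) per cohort. Fold subsetting is unbiased for
the null AUC because every scored patient's prediction is produced without
that patient in any training set; it only widens the Monte-Carlo error of the
across-seed mean, which the acceptance band already covers.

## Known limitations

* Features are generated independently; real clinical covariance is absent.
* The Youden threshold is selected on the evaluation scores (as published);
  reported accuracy/sensitivity/specificity are optimistic.
* The chi-square test's nominal level is unreliable for near-constant binary
  features (history of endometriosis is present in 1.6% of patients): in
  small under-sampled training sets such features are often constant (p = 1
  by convention) and otherwise yield tables too sparse for the asymptotic
  null, so their significance frequency sits near 0%, not near the nominal
  10% — matching the published observation that this feature never emerges
  as important.
* Proximity imputation with one global donor per recipient ignores scale
  heterogeneity across features and cannot express uncertainty; it is the
  published algorithm, not a recommendation.
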