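---
title: "Intent networks and lethality prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intent networks and lethality prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

People who attempt suicide communicate and act in patterned ways before the
attempt. The 15-item Beck Suicide Intent Scale (SIS) records those
antecedents — objective circumstances (items 1–8: isolation, timing,
precautions against discovery, help-seeking, final acts, preparation,
suicide note, overt communication) and self-reported intent (items 9–15:
alleged purpose, expectation of fatality, conception of the method's
lethality, seriousness, attitude toward living, conception of medical
rescuability, premeditation). Each item is scored 0–2. The medical outcome
of the attempt is graded 1–6 on the Columbia Suicide Severity Rating Scale
(C-SSRS) actual-lethality scale, from no physical damage to death.

`intentnet` implements a complete analysis of such cohorts:

1. **Preprocessing**: calibration of SIS scores to 1–3, decimal-year
   encoding of calendar dates, dichotomization of the C-SSRS grade, and
   k-nearest-neighbour imputation.
2. **Pairwise relationship signatures** over all 105 SIS item pairs.
3. **Group-wise partial-correlation networks** (graphical lasso with
   permutation-tested edges) contrasting lethal and nonlethal attempts.
4. **E-GONet**, a small convolutional classifier of attempt lethality on an
   18×20 feature grid, with linear-regression and random-forest baselines.
5. **Evaluation** by stratified cross-validation with precision-recall-gain
   metrics, and **Gradient×Input saliency** maps.

Because the underlying survey data are not public, the package ships a
seeded synthetic-cohort generator that reproduces the cohort's published
statistical structure; every downstream stage is developed and tested
against it.

# Cohort model and preprocessing

A cohort is a CSV with one row per subject: 15 raw SIS items (`sis_1` …
`sis_15`, ordinal 0–2), 14 emergency-room confounders, and the C-SSRS grade
(1–6). Empty cells are missing. The confounders are sex (1 = male,
2 = female), age (years), marital status (1–6), religion (1–5), monthly
income (currency units), living status (1–4), education (1–5), urbanicity
(1–3), ER visit date, weekend visit (1–2), ER visit hour (0–23), admission
route, admission transport, and discharge date.

**Calibration.** Raw 0–2 scores are shifted to 1–3 before any relationship
signature is computed. Strictly positive scores keep the harmonic mean
well-defined and give the tangent signature a bounded, symmetric range.

**Dates.** Calendar dates become decimal years:
`year + (day_of_year − 1)/366`, reported to three decimals, so 2013-06-30
encodes as 2013.492. The 366 denominator is deliberate: the alternative
(÷365) encodes that worked example as 2013.493, not the published 2013.492.
Within a year the encoding is strictly increasing day over day.

**Lethality label.** An attempt is lethal iff the C-SSRS grade is ≥ 4
(moderately severe physical damage, severe damage, or death). The published
cohort's grade counts (177/387/358/152/33/5 for grades 1–6) give exactly
190 lethal and 922 nonlethal subjects under this rule, which pins down the
cutoff despite inconsistent verbal statements of it.

**Imputation.** Missing cells are filled by k nearest neighbours (default
k = 10). Distances are root-mean-square differences over the standardized
columns observed in both subjects; coded/ordinal columns take the neighbour
mode (ties toward the smaller code), continuous columns the mean. Observed
cells are never altered, and imputation runs on the raw 0–2 SIS scores
(before calibration) and on encoded dates. The upstream analysis names only
the algorithm, not k, the metric or the aggregation; the defaults here are
the common conventions of kNN imputation packages and are recorded in a
JSON provenance sidecar per run.

# The synthetic cohort: a stated world

`generator_config()` defaults restate the published cohort structure:

| Quantity | Default | Source |
|---|---|---|
| n | 1112 | cohort size after exclusions |
| lethal prevalence | 0.171 | 190/1112 |
| male fraction, lethal / nonlethal | 0.563 / 0.387 | published counts |
| mean age (SD), lethal / nonlethal | 47.3 (18.4) / 42.3 (18.1) years | published means |
| missingness | 2.7% MCAR over SIS + confounder cells | published rate |
| C-SSRS grades within group | 152:33:5 (lethal 4:5:6), 177:387:358 (nonlethal 1:2:3) | published table |
| visit window | 2013-05-01 – 2013-11-07 | study window |

SIS items are generated by a Gaussian copula: per group, a latent
multivariate normal draw with a planted correlation matrix, discretized at
the fixed standard-normal tertiles (±0.4307), so each raw category has
probability 1/3 under a zero mean. The lethal group's latent means for
items 10–12 are raised by 0.5 SD by default, reproducing the direction of
the published group difference in SIS totals without targeting its exact
size.

The **planted partial-correlation structure** encodes the qualitative
finding the network stage must recover: the lethal group has a hub at item
11 (conception of the method's lethality) connected to items 10
(expectation of fatality) and 12 (seriousness), with partial correlation
0.40; the nonlethal group has a hub at item 9 (alleged purpose) while
items 10 and 11 are completely disconnected. Sparse extra links are
disjoint pairs (partial correlation 0.30–0.35) so each hub is strictly the
highest-degree node of its group. The planted truth (edge support and hub)
is returned alongside every generated cohort and is derived from the
inverse of the correlation matrix itself, not stored independently.

Confounders are plausibility fillers with no planted outcome signal except
the sex and age shifts: coded categories uniform over their legal codes,
log-normal income, visit dates uniform over the study window with the
weekend flag derived from the actual weekday, discharge lagging the visit
by a Poisson(3) number of days. This matches the saliency finding that
most confounders were negligible.

What the generator does **not** emulate — so what a green test does not
establish: the 17-centre structure and any between-centre heterogeneity,
repeat attempters, temporal dynamics, measurement error in SIS scoring,
informative missingness (masking is MCAR), or any confounder–outcome
dependence beyond age and sex. Tests against this world validate the
machinery (recovery of planted structure, direction of effects), not the
published effect sizes, which were computed on the non-public survey.

One master seed drives everything; each stochastic component draws from a
deterministically derived substream (`derive_seed()`), so identical seeds
give bitwise-identical cohorts.

# Relationship signatures

For each pair (i < j) of calibrated scores and each subject, three
signatures:

* interaction `I = s_i · s_j` ∈ [1, 9] — joint elevation;
* harmonic mean `H = 2 s_i s_j / (s_i + s_j)` ∈ [1, 3] — overall intensity,
  more sensitive to the smaller score than the arithmetic mean;
* tangent of the angle difference
  `T = tan(arctan s_i − arctan s_j) = (s_i − s_j)/(1 + s_i s_j)`
  ∈ [−0.5, 0.5] — an antisymmetric scalar that distinguishes the ordering
  of the pair ((2,3) vs (3,2)).

The defining equations upstream sit in an image we could not read; these
forms follow the verbal definitions exactly (an interaction term, a
harmonic mean, a tangent of an angle difference that is order-sensitive)
and each lives behind one exported function, so a swap is a one-line
change if the original source resurfaces.

The 105 pairs × 3 types give 315 features, ordered pair-major
(lexicographic pairs, I, H, T within each pair). Together with the 15
calibrated items and 14 confounders they fill an 18×20 grid row-major:
positions 0–14 SIS, 15–28 confounders, 29–35 structural zeros, 36–350
relationship features, 351–359 structural zeros. `grid_layout()` documents
every cell; the structural-zero blocks are exactly where the published
architecture diagram draws its two blank blocks.

# Group networks

Per outcome group, the node set is the 15 calibrated SIS items plus the
raw C-SSRS grade ("Fatality", 16 nodes). The graphical lasso is fitted to
the Pearson correlation matrix (block coordinate descent; at penalty 0 the
exact inverse is used), and edges are the implied partial correlations
`−Θ_ij/√(Θ_ii Θ_jj)`. The penalty is chosen by EBIC with γ = 0.5 over a
30-point log-spaced grid up to the largest absolute correlation — the
standard convention of the network-psychometrics stack. Pearson on the
1–3 ordinal scores is the default (the upstream analysis states nothing
finer); a polychoric pre-step was considered and rejected as out of scope
since edge inference is permutation-based, not likelihood-based.

Edge significance is a column-permutation test: every column is shuffled
independently (destroying all dependence, preserving marginals), the lasso
is refitted at the observed-data penalty, and the two-sided empirical
p-value is `(1 + #{|null| ≥ |observed|})/(n_perm + 1)` — the +1 correction
avoids zero p-values. An edge is significant when p < α (default .05) and
the observed weight is nonzero. Whether the Fatality column should be held
fixed under the null is not decidable from the upstream description; both
variants are implemented (`permute_all`), all-columns is the default. The
upstream analysis used 10,000 permutations; a few hundred give stable
decisions at α = .05 and are the test-suite default.

Topology reports degree (count of significant incident edges) and the
per-node mean unweighted shortest path within the node's component.
Isolated nodes get path length `NA` — not infinity — so topology bar
charts omit them, matching the published figures' treatment.

# E-GONet

The classifier is a small CNN on the 18×20 grid: three 3×3 same-padded
convolutions (16/32/64 channels, ReLU), 2×2 max-pooling after the first
two (18×20 → 9×10 → 4×5), then fully connected 1280 → 128 → 2 with
dropout 0.25 after the first FC layer, softmax cross-entropy, Adam at
1e-3, batch 64, 100 epochs. The published description fixes only the
topology (three conv + two FC layers, 18×20 input); the sizes above are a
conventional small-CNN reading of it, exposed in `egonet_config()` so they
can be aligned with the original if its appendices surface. Training is
exactly reproducible: weight initialization (He), shuffling and dropout
all draw from one config seed, and prediction is RNG-free.

The implementation is im2col + BLAS matrix products with the index-heavy
kernels (im2col/col2im, pooling, axis swaps) in C++; backpropagation
reaches the input grid, which is what the saliency module needs. There is
no GPU path and no hyperparameter search, and no resampling or
cost-sensitive loss: the upstream study reports that over/under-sampling
and SMOTE did not help at this prevalence.

Min–max scaling to [0, 1] is fitted per grid cell on training folds only;
constant cells (including the structural zeros) map to 0 and unseen values
clip to [0, 1]. The baselines consume the same flattened 360-cell grid, so
model comparisons isolate the architecture: "linear regression" is least
squares on the 0/1 target thresholded at 0.5 (the classical reading of
that model name; a logistic option exists behind a flag), with a 1e-8
ridge jitter for the always-singular design (structural-zero columns); the
random forest is a bagged CART forest (gini, mtry = √p, 500 trees),
written in-package because no forest implementation is available in the
target environment.

# Evaluation

Cross-validation is stratified (each fold's class ratio within one subject
of the global ratio): at prevalence ≈ 0.17 and k = 10, unstratified folds
can lose all positives from a test fold. Metrics per fold: weighted F1
(class-support-weighted mean of the two per-class F1 scores), PPV, NPV,
sensitivity, specificity, accuracy, and AUPRG. Ratios with zero
denominators are reported as 0 and flagged — consistent with reporting a
precision of 0.0 for an all-negative predictor rather than dropping it.
Standard deviations are reported separately across folds within a trial
and across repeated trials.

The precision-recall-gain curve rescales precision and recall against the
prevalence baseline π: `gain = (value − π)/((1 − π)·value)`, so the
always-positive classifier sits at recall gain 1, precision gain 0, and a
no-skill classifier has zero area. Operating points are the distinct score
thresholds (ties collapsed). Points with negative recall gain (recall
below prevalence) are dropped after being used to interpolate the curve's
crossing of recall gain 0; when even the top-ranked point already has
non-negative recall gain, the curve is anchored at recall gain 0 with that
point's precision gain. The area is the trapezoid over recall gain in
[0, 1]. Negative precision gains are retained (the construction allows
them), so AUPRG can be negative for a worse-than-baseline ranker and is 1
for a perfect one. An independent brute-force implementation of the same
construction is kept in the test suite and fuzz-compared to 1e-12.

# Saliency

Gradient×Input attributes each input cell the product of its value and the
gradient of a class's pre-softmax logit with respect to it. The target is
the subject's true class by default (configurable to the predicted class),
and signed importances are retained — averaging signed values shows
direction, and the absolute value is taken only at analysis time. Cells
that are structurally zero get importance exactly zero. The per-class map
is a two-stage mean, matching the upstream procedure: within each
cross-validation fold, maps of that fold's held-out subjects are averaged
per class; the fold means are then averaged. Folds lacking a class are
skipped with a flag.

# Numerical and design notes

* Lethality cutoff ≥ 4: forced by the published grade-count arithmetic
  (152 + 33 + 5 = 190); verbal statements of the cutoff conflict.
* Decimal-year denominator 366: reproduces the published worked example.
* Grade probabilities in the generator are the exact published fractions
  (e.g. 152/190), not rounded restatements.
* The graphical lasso inner loop converges to 1e-8 on coefficients;
  penalty 0 short-circuits to direct inversion (the MLE), which the test
  suite checks against brute force at 1e-6.
* Permutation p-values can never be 0 (+1 correction) and never resolve
  below 1/(n_perm+1); requesting α below that resolution warns.
* Degenerate scaler cells map to 0 by convention; predictions clip linear
  scores to [0, 1].
* kNN imputation requires at least k eligible neighbours per missing cell
  and errors on columns that are entirely missing.

# Test scaling and limitations

The acceptance-style tests run the full protocols at reduced scale so the
suite fits a desk-scale compute budget: the ablation-direction comparison
(E-GONet with vs without relationship features, on cohorts whose signal
lives only in the pairwise SIS structure) uses 5-fold CV, a narrower 8/16/32-channel configuration and 25 epochs
over 5 seeds rather than 10 folds × 100 epochs; the planted-network recovery runs 200
permutations rather than 10,000. What these tests establish is direction
and recovery in the stated synthetic world — not the published effect
sizes, which belong to data this package cannot access. The published
headline metrics (mean F1 0.81, AUPRG 0.73, etc.) are therefore
deliberately not asserted anywhere.
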