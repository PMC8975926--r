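---
title: "Methods: genotypes, chronotypes, and anxiety in chronoanx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotypes, chronotypes, and anxiety in chronoanx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoanx)
```

`chronoanx` is a pipeline for candidate-gene association analysis of anxiety
symptoms with circadian clock genotypes, diurnal preference, and molecular
chronotype. This vignette documents the models, the tunable parameters and
their defaults, the design choices made where the design was genuinely open,
and what the synthetic-data tests do and do not establish about real data.

## 1. The synthetic cohort generator

All stages are exercised on cohorts from `simulate_cohort()`, which emulates
the data structure of a deeply phenotyped candidate-gene study:

* **Genotypes.** Seven loci (`default_loci()`: CLOCK3111, CRY1, CRY2, PER2,
  PER3A, PER3B, and the PER3 VNTR) drawn independently at Hardy–Weinberg
  proportions p², 2pq, q². Minor-allele frequencies (0.15–0.45) are generator
  defaults in the common-variant range, not estimates of any real cohort.
  Loci are independent by design: linkage disequilibrium is out of scope.
* **Outcome.** A latent logistic model produces the binary high-anxiety
  class; the continuous STAI score is then drawn uniformly inside the class
  band — 45–80 for the high-anxiety class, 20–44 otherwise. The two-stage
  construction keeps the continuous score and the binary class coherent, so
  both the regression analyses (on STAI) and the classification analyses (on
  the class) see the same planted effects. The instrument's bands (20–37
  none/low, 38–44 moderate, 45–80 high) motivate the default classification
  cutoff of 45; 38 is the supported alternative.
* **Diurnal preference.** MEQ ~ round(Normal(50, 10)), truncated to the
  instrument range 16–86, plus per-genotype mean shifts (`mediation`): this
  is the genotype → MEQ → anxiety indirect pathway, realized when
  `meq_logOR_per_point` is non-zero.
* **Latent circadian phase.** phase = slope·(MEQ − 50) + Normal(0,
  `phase_sd`). The default slope of −0.08 h per MEQ point advances morning
  types; the direction is the established one, the magnitude is a package
  choice (no published per-point slope exists). Default `phase_sd` 1.5 h
  keeps most subjects within ±4 h of the reference. Misalignment is defined
  on this latent phase (z > 1 and MEQ < 41) and can carry its own log-OR.
* **Demographics.** Sex counts are fixed exactly (study scale: 318 males,
  664 females of n = 982); age group is Bernoulli(0.75) for the younger
  (≤ 22) class, matching a student-heavy cohort; the 4-level SES factor is
  sampled independently of the outcome, since no SES effect is part of the
  design.

Ground truth (latent log-odds, phase, phase z, misalignment flag) is kept in
dot-prefixed columns so recovery tests can compare estimates against truth;
no analysis stage reads them.

`simulate_expression()` samples a 24-h cosinor per subject × gene at
configurable clock times (default 8, 16, 17, 20 h — a realistic sparse
daytime design), with amplitude uniform in 0.8–2.0, the subject's latent
phase shift applied to the gene's reference acrophase, optional per-gene
jitter, and additive Gaussian noise (default SD 0.2).

**What the generator does not emulate:** linkage disequilibrium, genotyping
error, population stratification, non-uniform STAI distributions within
class bands, missing-not-at-random patterns, and assay-level qPCR noise
structure. Passing tests therefore demonstrate that the *methods* recover
what they claim under their stated assumptions — not that any particular
real-cohort estimate is correct.

## 2. Feature engineering

`encode_features()` one-hot encodes each tri-state locus *minus its most
frequent state* (the reference), appends all C(7,2) = 21 two-way genotype
combinations (up to 9 joint states each, again minus the most frequent joint
state — up to 8 indicators per pair), and adds the clinical features (MEQ
continuous; sex, age binary; SES one-hot minus reference). Choices:

* Reference ties break lexicographically, for determinism.
* A missing genotype makes *all* indicators of its group(s) `NA` rather than
  0 — a zero would silently assert the reference state. `impute_knn()`
  (unweighted mean of the k = 5 nearest rows, Euclidean distance on mutually
  observed unit-variance-scaled columns) fills them; it is idempotent and
  never alters observed entries.
* The realized feature count is cohort-dependent (states or joint states
  unobserved in a sample contribute no column), so no fixed total is
  asserted anywhere.

`smote_balance()` implements SMOTE with k = 5: synthetic minority points are
`x_i + λ(x_nn − x_i)`, λ ~ U(0,1), drawn along segments between minority
neighbours, never modifying or removing original rows. Inside
cross-validation SMOTE is applied to training folds only — balancing
validation folds would leak and flatter every classifier.

## 3. Feature selection and classification

Four criteria: information gain and ReliefF rank features; mRMR
(`I(X;Y) − mean_s I(X;X_s)`) and JMI (`Σ_s I(X,X_s;Y)`) select greedily,
both starting from argmax `I(X;Y)`. All information quantities are plug-in
estimates in bits on discretized data: continuous features are
equal-frequency binned (default 4 bins); integer-valued features with ≤ 12
levels pass through untouched so discrete data is handled exactly. ReliefF
defaults: k = 10 neighbours, all instances as sample points (deterministic).
Ties in every ranking break lexicographically.

The selection protocol runs each method once per fold of a repeated
stratified cross-validation (default 10 × 10 = 100 runs). A feature is
**robust** when it appears in ≥ 95% of a method's runs for ≥ 3 of the 4
methods (both thresholds inclusive, both configurable). By default selection
happens inside each fold's training part; `whole_data = TRUE` reproduces
protocols that derive the robust set from the full cohort (at the price of
optimistic downstream reuse — which is why it is not the default).

`crossval_evaluate()` scores random forests (`ranger`), boosted trees
(`xgboost`), and a linear-kernel SVM (`e1071`), plus a majority-class
reference, on accuracy and AUROC. The per-fold pipeline is leakage-safe:
training folds are imputed on their own rows; validation rows are imputed
using training rows as the only donors; selection, SMOTE, and the small
hyperparameter grid search (inner 3-fold) all see training data only. On a
balanced dataset the majority/permuted-label baseline is 50%; flexible
learners under permuted labels sit slightly *below* 50% by the usual
finite-sample pessimism of cross-validation, which is why the baseline is
defined by the reference classifier.

## 4. Association statistics

* `logistic_risk_table()`: per-feature (univariate, one-hot families kept
  together, with a group likelihood-ratio p alongside per-coefficient Wald
  p) or joint (multivariate) logistic fits; odds ratios with Wald 95% CIs;
  Benjamini–Hochberg adjustment across the table. Numerical separation is
  flagged with an infinite-OR sentinel instead of failing.
* `subset_search()`: sequential replacement over add / drop / swap moves
  accepted while AIC or BIC improves; ties prefer the smaller subset, then
  lexicographic order, so the search is deterministic.
* `fisher_cutoff_heatmap()`: cells are log₁₀ of the two-sided Fisher exact p
  for `[x > x_c] × [y ≥ y_c]`. The two-sided p follows the "sum of tables no
  more probable than observed" convention and is computed in-package from
  the hypergeometric pmf (`fisher2x2_p`), which makes dense cutoff scans
  cheap; `stats::fisher.test` serves as the independent oracle in the test
  suite. Rows of the exported matrix are anxiety cutoffs ascending, columns
  phenotype cutoffs ascending; display values are capped at log₁₀(1e−10);
  cutoffs that empty a margin give p = 1 with a mask flag.
* `anova_type3()`: type-III sums of squares under sum-to-zero contrasts
  (via `car::Anova`), with Tukey-adjusted pairwise cell-mean contrasts from
  `emmeans` — the standard sex × genotype-combination analysis of mean
  anxiety scores.
* `mediation_bootstrap()`: product-of-paths ACME for linear outcomes
  (`total = ACME + ADE` exactly); counterfactual composition on the response
  scale for binary outcomes. Percentile intervals from B = 1000 (default)
  nonparametric resamples — the simplest defensible interval for a
  nonparametric bootstrap; BCa is deliberately not implemented.

## 5. Rule mining and mutual-information networks

`mine_rules()` is a level-wise Apriori with downward-closure pruning
(support anti-monotonicity is asserted during mining). Retained rules
predict a target class, have length ≤ 6 (antecedent + consequent) and
confidence ≥ 0.9 — the protocol's constraints — and are ranked by lift with
confidence/support/lexicographic tie-breaks. A support floor is required for
tractability and none is prescribed by the protocol, so the default is 0.05,
configurable. Continuous items are discretized with the same equal-frequency
bins as feature selection, so both stages share one item universe.
Sex-stratified networks put antecedent items as nodes (sized by rule
co-occurrence) and weight edges by co-occurrence count and mean lift.

`mutual_information_matrix()` + `dpi_prune()` implement ARACNE: plug-in MI
for every pair, then for every fully connected triplet the weakest edge is
dropped when it is weaker than both others by more than ε. Defaults: ε = 0
(strict data-processing inequality), complete initial graph (no MI
significance floor), undirected edges — MI is symmetric and the package
makes no causal-direction claims. `aracne_bootstrap()` resamples subjects
with replacement and reports, per edge, the fraction of replicates in which
it survives pruning; no "robust link" threshold is imposed on these
confidences — they are reported raw.

## 6. Molecular chronotyping

The oscillation model is a single-harmonic 24-h cosinor
`M + A·cos(2π(t − φ)/24)` — the minimal form consistent with phase and
amplitude outputs; it sits behind one interface (`oscillation_model()` /
`oscillation_value()`) so a richer curve model can be slotted in. Fitting
minimizes the SSE over the subject's (z-scored) points with SRES, on the
linear parameterization `(a, b, M)` with `a = A cos`, `b = A sin` — the
phase is recovered by `atan2`, so there is no 0/24-h boundary artifact.

SRES is a (μ, λ) evolution strategy with log-normal step-size
self-adaptation and stochastic-ranking bubble sort: adjacent candidates are
compared by objective with probability Pf when constraint violations are
involved, by violation otherwise; fully feasible populations rank purely by
objective. Defaults λ = 200, μ = 30, G = 300, Pf = 0.45, bounds
|a|, |b| ≤ 5, |M| ≤ 3 — canonical stochastic-ranking settings. The
training-curve parameters are seeded into each subject's initial population,
so a subject's fitted SSE can never exceed the training curve's own SSE on
their points, and the best-so-far trace is non-increasing.

The training curve averages z-scored values per timepoint across reference
subjects (ideally known intermediate chronotypes) and fits the cosinor to
the averaged points; an antiphase-cancelled (amplitude < 0.01) curve is
flagged degenerate. The phase shift is `training φ − subject φ` wrapped to
(−12, 12]; **positive = advanced (earlier peak)**. Phase shifts and
amplitudes are z-scored across the cohort per gene (not pooled across
genes). Misalignment defaults: phase z > 1 *and* MEQ < 41 (the conventional
evening-type boundary) — both configurable, since no published operational
thresholds exist; morning types are never flagged regardless of phase. The
misalignment odds ratio comes from a logistic fit of anxiety on the flag,
with Wald 95% CI.

## 7. Pipeline, reproducibility, and problem sizes

`run_pipeline()` executes simulate → encode → select → classify → stats →
rules → network → chronotype → report from one validated configuration
(`default_config()`; unknown keys are rejected). One master seed
deterministically spawns per-stage seeds, so stages can be reproduced in
isolation; identical configurations give byte-identical result tables, and
the report manifest records the config, seed, and checksums of every
artifact.

The test-suite and acceptance-script problem sizes are the package's own
choices balancing statistical resolution against desk-scale runtimes:
planted-effect recoveries run at n = 20,000 (epistatic and misalignment odds
ratios) and n = 2,000 (mediation, B = 500); phase recovery uses 200 subjects
at noise SD 0.2 with a reduced SRES budget (λ = 100, G = 150), which is
ample for a 3-parameter fit; oracle equivalences enumerate all 2×2 tables
with N ≤ 40 and a 10-item rule universe; null calibration uses 600
replicates (binomial SE ≈ 0.9% on a 95% coverage estimate). Pipeline smoke
configurations (n ≈ 120, 3-fold CV) exercise wiring, not power.

## 8. Known limitations

* The cosinor is a single harmonic; strongly non-sinusoidal expression
  profiles will fold their shape error into amplitude/phase estimates.
* Four timepoints identify a 3-parameter fit with 1 residual degree of
  freedom; per-subject SSE is therefore a weak lack-of-fit measure, and
  cohort-level z-scores carry the interpretive weight.
* Plug-in MI is biased upward at small n; the package applies no bias
  correction, matching the plug-in convention used across all its criteria.
* The robust-feature rule's type-I behaviour is verified at smoke scale on
  null cohorts; its power depends on cohort size and effect structure and is
  not characterized exhaustively.
* Synthetic cohorts omit LD, stratification, and instrument-level noise (see
  §1); conclusions about real data require real data.
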