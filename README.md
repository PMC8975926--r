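# chronoanx

Circadian clock genotypes, diurnal preference, molecular chronotype, and
anxiety risk — an end-to-end, reproducible analysis pipeline in R.

## The problem

Anxiety symptoms are associated both with polymorphisms in core circadian
clock genes (*CLOCK*, *CRY1/2*, *PER2/3*) and with disruptions of circadian
rhythms themselves. Candidate-gene studies of deeply phenotyped cohorts probe
these links on three levels:

1. **Genotype → anxiety**, including *epistatic* (two-locus) genotype
   combinations that carry more risk than any single variant;
2. **Genotype → diurnal preference → anxiety**, i.e. mediation of genetic
   effects through morningness–eveningness (MEQ);
3. **Molecular chronotype → anxiety**: the phase and amplitude of clock-gene
   expression oscillations, estimated per subject from sparse (4-timepoint)
   hair-follicle sampling, and *circadian misalignment* — an advanced
   molecular phase in a behaviourally evening-type person.

`chronoanx` implements the full analysis stack used for such studies as a
tested R package: epistatic feature encoding, robust feature selection by
four criteria (information gain, ReliefF, mRMR, JMI) with a 95%-of-runs /
3-of-4-methods aggregation rule, SMOTE-balanced leakage-safe repeated
stratified cross-validation of random-forest / boosted-tree / max-margin
classifiers, logistic risk tables with Benjamini–Hochberg adjustment and
AIC/BIC sequential-replacement subset search, Fisher exact cutoff-scan
heatmaps, type-III two-way ANOVA with Tukey follow-up, nonparametric
bootstrap mediation (ACME/ADE), Apriori association-rule mining with lift
ranking and sex-stratified rule networks, ARACNE mutual-information networks
with data-processing-inequality pruning and bootstrap edge confidence, and
molecular chronotyping by constrained cosinor fitting with a
stochastic-ranking evolution strategy (SRES).

Because raw human cohort data of this kind is not publicly available, the
package ships a first-class **synthetic cohort generator** with plantable
effects (genotype main effects, epistatic odds ratios, sex/age effects,
genotype→MEQ→anxiety mediation, phase/amplitude structure with misalignment),
so every stage is testable end to end from a single seed.

## The core models

*Anxiety generation/analysis.* The binary high-anxiety class (STAI ≥ 45 on
the 20–80 trait scale) follows a logistic model

&nbsp;&nbsp;logit P(anxiety) = β₀ + Σ βg·1[genotype g] + Σ βgh·1[genotype
pair (g,h)] + β_sex·sex + β_age·age + β_meq·(MEQ − 50) + β_mis·misaligned,

and the analysis stages recover the βs as odds ratios with Wald CIs.

*Molecular chronotype.* Expression at clock time *t* follows a 24-h cosinor
`y(t) = M + A·cos(2π(t − φ)/24)`. Each subject's `(A, φ, M)` is fitted to
their z-scored 4-point series by SRES on a sin/cos parameterization; the
phase shift is the circular difference between the reference (training-curve)
acrophase and the subject's, wrapped to (−12, 12] h, positive = advanced.
Misalignment = advanced phase z-score (> 1 SD) *and* evening preference
(MEQ < 41).

*Mediation.* For continuous outcomes, ACME = a·b from mediator model
`M ~ T + C` and outcome model `Y ~ M + T + C`, with percentile CIs from
nonparametric bootstrap resampling of subjects; `total = ACME + ADE` holds
exactly in the linear case.

## Worked example

Plant the study-scale cohort (n = 982; 318 males, 664 females) with a strong
epistatic pair effect (OR 15), demographic effects, and a misalignment odds
ratio of 6 — then recover them:

```r
library(chronoanx)

plan <- effect_plan(intercept = -1.2,
                    pair_effects = c("PER3B_AG/CRY1_CG" = log(15)),
                    sex_logOR = 0.6, age_logOR = 1.3,
                    meq_logOR_per_point = -0.04,
                    misalignment_logOR = log(6))
cohort <- simulate_cohort(default_loci(), plan, n = 982,
                          sex_counts = c(318, 664), seed = 11)

y <- binarize_outcome(cohort$stai, cutoff = 45)
risk <- logistic_risk_table(
  dplyr::mutate(cohort, pair = as.integer(PER3B == "AG" & CRY1 == "CG")),
  y, features = c("pair", "sex", "age_group", "meq"))
risk
#> # A tibble: 4 × 9
#>   feature   group     odds_ratio ci_low ci_high  p_value p_group_lrt    p_adj
#> 1 pair      pair          12.7    6.38   25.2   4.20e-13    1.32e-23 1.68e-12
#> 2 sex       sex            1.36   1.03    1.78  2.92e- 2    2.95e- 2 2.92e- 2
#> 3 age_group age_group      2.90   2.16    3.90  1.79e-12    1.14e-12 3.57e-12
#> 4 meq       meq            0.976  0.963   0.989 2.72e- 4    2.35e- 4 3.63e- 4

tidy(misalignment_risk(
  dplyr::tibble(phase_z = cohort$.phase_z, meq = cohort$meq,
                anxiety = cohort$anxiety)))
#> # A tibble: 1 × 7
#>   odds_ratio ci_low ci_high  p_value n_misaligned     n masked
#> 1       5.71   2.24    14.5 0.000258           49   982 FALSE
```

The planted pair effect (OR 15) comes back as 12.7 (CI 6.4–25.2) at this
cohort size; the planted misalignment OR 6 comes back as 5.7 (CI 2.2–14.5)
with 49 of 982 subjects flagged misaligned; the protective MEQ effect
(OR 0.976 per point) and the female and young-adult risk effects are all
detected. The full pipeline — selection, classification, rules, networks,
chronotyping, report — runs from one config with `run_pipeline()`
(see the methods vignette in `vignettes/`).

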