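Package: chronoanx
Title: Circadian Clock Genotypes, Molecular Chronotype, and Anxiety Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible analysis pipeline linking circadian
    clock gene polymorphisms, diurnal preference, and expression-derived
    molecular chronotype to anxiety symptoms. Provides a seeded synthetic
    cohort generator with plantable genotype, epistatic, mediation, and
    circadian-misalignment effects; epistatic one-hot feature encoding with
    k-nearest-neighbour imputation and SMOTE class balancing; four
    information-theoretic and relief-based feature-selection criteria with a
    robustness aggregation rule and leakage-safe repeated stratified
    cross-validation of random-forest, boosted-tree, and support-vector
    classifiers; logistic risk tables with Benjamini-Hochberg adjustment and
    AIC/BIC sequential-replacement subset search; Fisher exact cutoff-scan
    heatmaps; type-III two-way ANOVA with Tukey follow-up; nonparametric
    bootstrap mediation; Apriori association-rule mining with lift ranking
    and sex-stratified rule networks; ARACNE-style mutual-information network
    inference with data-processing-inequality pruning and bootstrap edge
    confidence; and molecular chronotyping by constrained cosinor fitting
    with a stochastic-ranking evolution strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    ranger,
    xgboost,
    e1071,
    pROC,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
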