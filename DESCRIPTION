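Package: nddprs
Title: Polygenic Risk Scoring and Antipsychotic Responsiveness Analysis for
    Schizophrenia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline linking polygenic risk for
    neurodevelopmental disorders (ADHD, ASD) to antipsychotic responsiveness
    in schizophrenia. Provides genotype quality control with an exact
    Hardy-Weinberg test, clumping-and-thresholding polygenic risk scores with
    Nagelkerke R-squared threshold selection, the antipsychotic
    responsiveness score (ARS) derived from DIBS symptom-scale timelines and
    chlorpromazine-equivalent dose, Spearman/Benjamini-Hochberg association
    batteries with exact small-sample tests, negative-binomial GLM
    differential expression between PRS-defined subgroups with Cox-Reid
    dispersion estimation and TMM normalization, and hypergeometric gene-set
    over-representation analysis. A synthetic-cohort generator with block-LD
    genotypes, a liability-threshold phenotype, a rank-copula responsiveness
    model and negative-binomial counts makes every stage testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
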