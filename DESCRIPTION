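Package: wgwas
Title: Inverse-Probability-Weighted Genome-Wide Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring and correcting volunteer (participation)
    bias in genome-wide association studies. Estimates per-individual
    participation probabilities from a pooled reference-population/cohort
    table with an L1-penalised probit model, builds winsorised
    inverse-probability weights, runs unweighted (GWAS) and weighted
    (WGWAS) per-SNP association scans with heteroskedasticity-robust
    standard errors, and contrasts the two scans via per-SNP Hausman
    tests, effective sample sizes, LD clumping, top-hit slope regression
    and a simplified LD-score regression for observed-scale SNP
    heritability. A synthetic-cohort generator reproduces the selection
    scenarios (random, phenotype-related and phenotype-genotype-related
    participation) under which the estimators are validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
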