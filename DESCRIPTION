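Package: snpint
Title: SNP-SNP Interaction Screening and Interaction-Based Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-pattern search for pairwise SNP-SNP interactions associated
    with a binary disease outcome (such as prostate cancer aggressiveness),
    spanning additive, dominant, and recessive inheritance-mode encodings with
    original and reverse coding directions. Implements the 9-pattern
    additive-additive search and its 45-pattern extension with BIC-based model
    selection, a two-stage discovery/validation screening workflow with
    Bonferroni and replication criteria, construction of an interaction-based
    polygenic risk score with 7 risk strata and AUC comparison, two-way eQTL
    scanning under a linear link, genotype quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, LD pruning, principal
    components), PLINK and TSV readers, and a synthetic-data generator that
    emulates genotype panels with block LD structure, site/ancestry covariates,
    and logistic phenotypes at a calibrated prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
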