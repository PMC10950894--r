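Package: omixtwas
Title: Multi-Omic Transcriptome-Wide Association and Mediation Analysis with
    Epigenome-Informed Expression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-omic blood-pressure gene discovery in a target
    tissue: training of genetically regulated expression (GReX) models with a
    differential elastic-net penalty that relaxes shrinkage on epigenomically
    annotated variants and tunes the cis window over 3D-genome-informed
    candidates; summary-statistic transcriptome-wide association (TWAS) with
    reference-panel linkage disequilibrium; reciprocal two-cohort replication
    with Benjamini-Hochberg false discovery control; tissue prioritisation
    ranking; two-sample Mendelian randomization (inverse-variance weighted,
    penalized and MR-Egger, with correlated instruments) and two-step
    mediation with delta-method standard errors; conditional Z-score host-gene
    tests; probabilistic gene-level fine-mapping with posterior inclusion
    probabilities and credible sets; and a synthetic-data generator with
    planted truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    vcfR,
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
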