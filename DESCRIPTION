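Package: tmephenotyper
Title: Tumor Microenvironment Immune Phenotyping from Bulk Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-sample gene-set enrichment scoring (GSVA-style
    rank-walk) of immune and stromal cell types from gene expression
    matrices, k-means assignment of Hot/Moderate/Cold tumor immune
    phenotypes, the immune-stromal ratio statistic, a marker-panel
    classifier for normal, inflammatory and myofibroblast-like
    fibroblasts (NF/iCAF/myCAF), survival stratification by maximally
    selected log-rank cutpoints, phenotype-covariate association, and
    longitudinal phenotype-transition analysis across treatment
    timepoints. Includes a synthetic-cohort generator that emulates the
    statistical structure of multi-dataset breast cancer compilations so
    the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
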