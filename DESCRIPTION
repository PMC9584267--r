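Package: immunoharmonize
Title: Harmonization of Multi-Study Vaccine Transcriptomics Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assemble, quality-control and harmonize blood
    transcriptomics data collected across many vaccination studies on
    heterogeneous platforms, and to compute antibody-response endpoints.
    Provides per-array outlier statistics (pairwise-distance, Kolmogorov-
    Smirnov versus pooled intensities, Hoeffding's D on MA values) with a
    fail-all-three flagging rule, gene-alias resolution and probe collapsing,
    within-study quantile normalization, cross-study quantile normalization
    to an Affymetrix-derived target distribution, baseline-anchored
    estimation and removal of study/platform/specimen batch effects,
    principal variance component analysis (PVCA), Y-chromosome-based sex
    imputation, correlation-staging age imputation, and antibody titer
    endpoints (maximum fold change across strains and maximum residual after
    baseline adjustment). A synthetic multi-study compendium generator with
    recorded ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    lme4,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
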