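Package: panconet
Title: Multiscale Coexpression Network Modules and Their Prognostic and
    Epigenomic Regulation Across Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds planar maximally filtered coexpression networks (PMFG)
    from cohort expression matrices with a permutation-based FDR correlation
    threshold, decomposes them into a multiscale hierarchy of gene modules by
    recursive modularity optimization, and characterizes the modules:
    eigengene survival analysis (median-split Cox proportional hazards),
    Fisher's exact test enrichment against gene-set collections and
    chromosome cytobands, tumor-versus-normal differential expression and
    promoter CpG methylation with moderated t-statistics, cytoband-level
    chromatin accessibility contrasts, and cross-cohort module preservation
    (Jaccard/Fisher) with greedy module clustering and conservation-weighted
    network aggregation. Ships a seeded multi-cohort, multi-omic synthetic
    data generator with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    igraph,
    survival,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
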