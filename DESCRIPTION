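Package: wheatacr
Title: Accessible Chromatin and Homeolog Bias Analysis for Hexaploid Wheat
    Grain Development
Version: 0.1.0
Authors@R:
    person("Grain", "Regulome Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative ATAC-seq/RNA-seq toolkit for allohexaploid wheat
    grain development. Refines raw ATAC-seq peaks by Tn5 integration-site
    density filtering (150 bp sliding bins, Poisson background cutoff,
    merge, blacklist masking), annotates accessible chromatin regions (ACRs)
    as genic, proximal or distal, clusters differential accessibility and
    expression into eight tissue-specificity groups, classifies homeolog
    triads into seven ternary bias categories for both expression and
    promoter accessibility, profiles motif density per cluster and
    subgenome, and builds stage-resolved TF-to-target regulatory networks.
    Ships a fully labelled synthetic hexaploid genome generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    limma,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
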