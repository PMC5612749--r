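Package: codomains
Title: Coexpression Domain Detection Along Chromosomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects coexpression domains (CODs), runs of neighbouring genes
    whose expression profiles are mutually correlated across samples, using a
    TopDom-style windowed boundary statistic (binsignal) on per-chromosome
    Pearson correlation matrices. Companion analyses cover intra- and
    inter-domain coexpression statistics with randomization null models
    (coordinate inversion and border shifting), detection of regions of
    increased gene expression (RIDGEs) by a moving-median rule, coincidence
    statistics between domain sets (CODs versus TADs or contact domains), and
    a Hi-C stack with Knight-Ruiz balancing, observed-over-expected
    normalization and contact-profile correlation related back to
    coexpression. A seeded synthetic-data generator plants known correlated
    gene blocks and compartmentalized contact maps so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, HiC, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
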