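Package: cisomr
Title: Cis-Overlapping Motif Detection and Sequence-to-Expression
    Analysis of Non-Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cis-overlapping motifs (CisOMs) of the tumor
    suppressor P53 and the proto-oncogene cMYC inside co-occupied
    ChIP-seq peak regions, scores every possible single-nucleotide
    variant in each CisOM by its change in position-weight-matrix
    predicted binding (delta-binding), and tests whether delta-binding
    correlates with allelic change in expression (delta-expression)
    using Spearman's rank correlation with an exact permutation p-value
    at small sample sizes. Includes a seeded synthetic-data generator
    that plants P53 half-site pairs and cMYC sites in a random genome
    so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    methods,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
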