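Package: hicdelta
Title: Differential Chromatin Interaction Detection for Hi-C Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting differential interactions between
    biological conditions in Hi-C data. Covers restriction-digest genome
    modelling, chimeric-read splitting at ligation signatures, read-pair
    quality control, counting into bin pairs, abundance-based filtering,
    offset-based normalization (loess trended, scaling, CNV surface,
    iterative correction), quasi-negative-binomial GLM testing with
    empirical-Bayes quasi-likelihood dispersions, multi-resolution
    consolidation with Simes combination, plaid-plot visualization, and
    a synthetic-data simulator for benchmarking against a binomial
    comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
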