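Package: rloopstat
Title: Permutation Overlap Enrichment and qPCR Quantitation for R-Loop
    Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for testing whether a set of genomic intervals
    (e.g. ChIP-seq peaks or R-loop prone regions) is enriched for a gene
    set of interest by resampling random gene sets from an annotation,
    with exact binomial confidence intervals on the permutation p-value;
    bead-control filtering of peak sets; selection of the top fraction of
    transcribed genes; overlap testing of top differentially expressed
    genes against peak regions; cycle-threshold (Ct) quantitation of
    ChIP-qPCR percent enrichment with mock subtraction, DRIP-qPCR fold
    enrichment over input, and comparative-Ct (2^-ddCt) fold changes; and
    seeded synthetic-data generators with known ground truth for every
    input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tidyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
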