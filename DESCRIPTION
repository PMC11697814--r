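Package: oostage
Title: Chromatin-Stage Inference and Methylome Dynamics in Mouse GV Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the NSN-to-SN chromatin transition of the
    fully-grown mouse germinal-vesicle oocyte. Provides transcriptome
    complexity statistics and a negative-binomial differential-expression
    test for single-oocyte RNA-seq counts, a 100-transcript nearest-centroid
    classifier that infers chromatin configuration (NSN or SN) from
    single-cell or bulk RNA-seq, an iterative pseudobulk consensus caller
    for differentially methylated regions in sparse single-cell bisulfite
    data, joint histone-mark categorization of 2-kb genome windows with
    interval-enrichment statistics, and seeded synthetic-data generators
    with planted ground truth for all three modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    MASS,
    Matrix,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
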