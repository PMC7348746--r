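Package: chipintegrate
Title: Integration of Histone-Mark ChIP-Seq with Expression for Bivalent
    Promoter and Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of histone-modification ChIP-seq peak and
    differential-enrichment calls integrated with gene-level expression in a
    two-age, two-group (control vs intrauterine growth restriction) design.
    Provides a genomic-region taxonomy for peak annotation, nearest-TSS
    assignment of differential sites, sign-concordance classification of
    mark versus expression changes, bivalent (poised) promoter calling from
    overlapping H3K4me3 and H3K27me3 peaks, classification of bivalency
    transitions across the four conditions, motif-enrichment persistence
    calls, input-normalised TSS metaprofiles, and a synthetic-data generator
    with a ground-truth manifest for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
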