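Package: mirstack
Title: Discovery and Characterization of miRNA Genes from Small RNA
    Sequencing Read Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A genome-wide microRNA discovery pipeline for species without a
    curated miRNA catalog. Raw small-RNA reads are collapsed to unique
    sequences with copy numbers, filtered by abundance and length, mapped to
    the genome by perfect match, and excluded when they resemble coding
    transcripts, repeats, or map to too many loci. Surviving loci are
    extended into candidate hairpin precursors, folded with a base-pair
    maximization dynamic program, summarized as ten structural features, and
    classified by a support vector machine with empirically calibrated
    p-values. Positive candidates are assembled into pre-miRNAs with per-arm
    isomiR stacks, split into homolog and novel sets against a known-miRNA
    catalog, and characterized by genomic clustering, arm-selection
    preference, and conservation-versus-expression quartile statistics. A
    synthetic-data module plants hairpins, repeats, and coding decoys with a
    full truth table so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
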