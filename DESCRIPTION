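Package: mirseedling
Title: Plant Small-RNA Processing, MicroRNA Discovery and Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for plant microRNA profiling from
    small RNA sequencing reads, built around the workflow used for the
    cumin (Cuminum cyminum) seedling miRNA study (NCBI SRA SRP376517):
    adapter trimming, quality and length filtering, read collapsing and
    non-coding RNA subtraction; conserved-miRNA classification by
    mismatch-tolerant matching against mature plant miRNA references;
    novel-miRNA discovery from hairpin precursors scored with a
    nearest-neighbour minimum-free-energy fold and the minimal folding
    free energy index (MFEI); plant-style miRNA target prediction with a
    position-weighted expectation score; MFE-weighted miRNA-target
    network export; and qPCR relative-expression computation normalised
    to an endogenous control. Includes a fully deterministic synthetic
    data generator with truth tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
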