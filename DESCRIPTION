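Package: whiteflydelim
Title: DNA Barcode Species Delimitation and Primer Evaluation for Whitefly
    mtCO1 Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for partial mitochondrial cytochrome
    oxidase 1 (mtCO1) barcode surveys of the Bemisia tabaci cryptic species
    complex: IUPAC-degenerate primer matching, mismatch profiling and
    in-silico PCR; pairwise p-distance and Kimura two-parameter divergence;
    percent-identity species delimitation against a labelled reference
    panel under the 3.5-4.0% divergence criterion with single- or
    complete-linkage clustering of unassignable queries into new putative
    species; neighbor-joining and UPGMA distance trees; fossil-calibrated
    strict-clock divergence dating with bootstrap confidence intervals; and
    a seeded synthetic-data generator (Yule trees, JC69/K2P sequence
    evolution, structured reference panels, primer-planted templates) so
    every stage runs reproducibly without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phytools,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
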