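Package: tesilence
Title: Transposable-Element Landscapes and piRNA Silencing in Drosophila Gonads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analysing transposable-element (TE)
    landscapes and PIWI-interacting RNA (piRNA) mediated silencing in gonadal
    tissues. Turns similarity-search hits into merged TE insertion annotations,
    computes per-family nucleotide diversity, classifies small-RNA reads and
    normalizes piRNA counts by miRNA abundance, quantifies ping-pong
    amplification signatures from 5'-5' read overlaps, screens the genome for
    piRNA clusters in fixed windows with tissue-specificity calls and TE
    density profiles, and correlates piRNA output with genomic traits of TE
    families. A fully seeded synthetic-data generator produces genomes, TE
    landscapes and small-RNA libraries with known ground truth so that every
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
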