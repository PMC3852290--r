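Package: teminer
Title: De Novo and Profile HMM Detection of Insertion Sequences and MITEs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for detecting prokaryotic transposable elements in
    genomes and metagenomic reads. Implements three complementary workflows:
    de novo mining of repeated-sequence families with greedy consensus
    extension, discovery of inverted-repeat-delimited elements with linking of
    MITEs (miniature inverted-repeat transposable elements) to their autonomous
    insertion-sequence partners, and a library-based search using protein
    profile hidden Markov models over six-frame-translated genome segments.
    The algorithmic cores (mismatch-tolerant inverted-repeat scanning, l-mer
    seeded repeat consensus building, greedy centroid clustering, seeded local
    alignment with Karlin-Altschul statistics, and profile HMM scoring with
    extreme-value calibration) are implemented natively. A synthetic-genome
    simulator with implanted elements and emitted ground truth makes every
    stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    stringi,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
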