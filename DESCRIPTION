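Package: srnakit
Title: Small RNA-Seq Annotation and Pre-miRNA Hairpin Classification
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for small RNA transcriptomics in early vertebrate
    development. Implements a support-vector-machine classifier of pre-miRNA
    hairpins built on 65 sequence and secondary-structure features
    (dinucleotide composition, triplet structure-sequence elements, pairing
    topology and minimum-free-energy ratios) with F-score feature-set
    selection, pseudo-hairpin negative-set construction from coding sequence,
    and cross-validated performance reporting (sensitivity, specificity,
    accuracy, Matthews correlation, ROC). Also implements a hierarchical
    small-RNAome annotator for collapsed read tags (miRNA, rRNA, tRNA,
    snRNA/snoRNA, repeat, mRNA, piRNA) with ncRNA recall from repeat
    annotations, repeat-associated piRNA rescue, fractional multi-mapping
    counts, isomiR-aware miRNA quantification, reads-per-million
    normalisation, piRNA cluster calling, seed-based miRNA family profiling
    and classifier-based triage of novel miRNA candidates. A seeded synthetic
    data generator produces every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    e1071,
    pROC,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
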