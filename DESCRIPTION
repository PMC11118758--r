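Package: rippmine
Title: Deep-Learning Metagenome Mining of RiPP Precursors and
    Prokaryote-Phage Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining ribosomally synthesized and
    post-translationally modified peptides (RiPPs) from fragmented
    metagenomic data and for linking them to prokaryote-phage
    interactions. Implements a Transformer-encoder plus bidirectional
    LSTM precursor classifier trained with focal loss (including the
    full training schedule, metric suite, cross-validation, and an
    identity-binned generalization benchmark), small-ORF admission
    rules, a genomic-context validity engine for predicted precursors,
    greedy identity clustering for dereplication, families and vOTUs,
    viral-contig triage with alternative genetic-code selection,
    CRISPR-spacer, tRNA and prophage host-phage linkage, and
    metatranscriptomic read-filtering, family abundance aggregation
    and hypergeometric module enrichment. Deterministic synthetic
    fixture generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
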