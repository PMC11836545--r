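Package: nervetcr
Title: Paired Blood-Nerve TCR-Beta Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired peripheral-blood and nerve-tissue T-cell
    receptor beta (TCR-beta) repertoires from amplicon sequencing. Provides a
    read-level pipeline (paired-end merging, 8 bp multiplex-identifier
    demultiplexing, V/J annotation against a germline reference, CDR3 quality
    filtering, clonotype calling, cross-subject contamination screening),
    highly-expanded-clone and impact statistics with paired-compartment
    overlap classification, CDR3 Hamming-distance clustering with a dynamic
    density-valley threshold, a probability model for detecting a clone's
    transcripts in a small blood sample, and a synthetic-data generator that
    emulates skewed paired repertoires for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
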