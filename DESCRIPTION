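Package: tcrdiv
Title: T-Cell Receptor Repertoire Diversity Profiles and Relational
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of T-cell receptor (TCR) repertoire
    diversity from targeted genomic DNA sequencing: tag-based V(D)J
    clonotype calling with UMI deduplication, Renyi-entropy diversity
    profiles over a grid of orders, depth-equalised Euclidean distance
    matrices between profiles, classical multidimensional scaling, and
    group classification with the Potential Support Vector Machine on
    relational (distance) data, assessed by leave-one-out
    cross-validation and label-permutation testing with Bonferroni
    family correction. Includes a synthetic-data module that simulates
    germline references, clonally expanded repertoires, cohorts, and
    UMI-tagged paired-end reads so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
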