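Package: plastomics
Title: Comparative Structural Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of plastomes
    (chloroplast genomes): detection of the inverted-repeat pair and the
    quadripartite LSC/SSC/IR partition by sequence self-comparison and by
    read-coverage doubling, quantification of inverted-repeat boundary
    expansion relative to an autotrophic outgroup, codon-frame-aware
    pseudogene calling (frameshifts and premature stop codons) against a
    functional reference, detection of inactivating mutations shared across
    species, and Dollo placement of gene-loss events on a fixed species
    tree. Includes a synthetic plastome evolution simulator with a ground
    truth ledger used to validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
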