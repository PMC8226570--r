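Package: porinperm
Title: Porin Permeability Scoring and Whole-Cell Accumulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating small-molecule permeability through
    Gram-negative outer-membrane general porins and relating it to
    whole-cell compound accumulation. Computes conformer-ensemble
    molecular descriptors (net charge, total and transversal dipole
    moment about the main inertia axis, minimal projection area and its
    fluctuation), scores compounds with an interaction-based
    log-permeability function for a cation-selective porin such as OmpF,
    expresses scores as a percentage of a glycine reference, and runs an
    accumulation analysis pipeline (filtering, categorisation,
    log-log regression). Includes a synthetic compound-table generator
    with a planted permeability-accumulation correlation so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
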