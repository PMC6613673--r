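Package: niptsim
Title: Hidden Markov Model Framework for Targeted High-Coverage cfDNA
    Aneuploidy Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis framework for targeted high-coverage
    sequencing based non-invasive prenatal testing (NIPT). Simulates
    cell-free DNA allele counts for euploid and meiosis-I trisomic
    pregnancies over grids of fetal fraction and read depth using
    over-dispersed negative binomial noise; estimates fetal fraction from
    allelic ratios of informative SNPs; classifies targeted loci with
    read-count (2-state), allelic-ratio (7-state) and combined bivariate
    hidden Markov models decoded by the Viterbi algorithm; and calls
    chromosome-level fetal condition by the modal decoded state, a depth-3
    decision tree, or a soft-margin kernel classifier on the decoded state
    frequencies. Includes the accuracy-grid, locus-subsampling and
    minor-allele-frequency experiments, and a read-count pipeline for
    experimental targeted count tables with interquartile-range locus
    filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rpart,
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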