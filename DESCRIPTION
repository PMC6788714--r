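Package: subdriver
Title: Detection Probability of Subclonal Driver Mutations in Growing Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for the cancer-cell frequency of a
    subclonal driver mutation in a two-type branching-process model of tumor
    growth. Computes the probability distribution of driver frequency at a
    given tumor size, the probability that the driver falls inside a
    detectable frequency window (the regime in which it can distort the
    neutral 1/f mutation-frequency spectrum), two-sequential-driver detection
    probabilities, and driver mutation-rate bounds. Includes exact Gillespie
    simulation of the well-mixed process, a 3d lattice tumor-growth model,
    and a two-clone logistic (sigmoidal) growth phase, used to validate the
    analytic results, plus grid-scan and figure-reproduction helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
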