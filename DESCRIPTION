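Package: ednaocc
Title: Two-Stage Bayesian Occupancy Modelling for eDNA Surveys with
    False Positives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a two-stage site-occupancy model to quantitative PCR
    (qPCR) detection histories from environmental DNA (eDNA) surveys,
    estimating occupancy alongside false-negative and false-positive
    error rates at both the water-sample (field) and qPCR-replicate
    (laboratory) levels. Occupancy probabilities are modelled on the
    logit scale with covariates via Polya-Gamma data augmentation, and
    covariate importance is assessed by spike-and-slab Bayesian variable
    selection with Add-Delete-Swap Metropolis moves. Includes a
    synthetic-survey generator matching the assumed data-generating
    process, posterior-predictive goodness-of-fit simulation, posterior
    conditional-absence probabilities given an observed number of
    amplifying replicates, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
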