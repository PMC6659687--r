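Package: viviphy
Title: Comparative Phylogenetics of Reproductive Mode, Sexual Selection,
    and Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether female reproductive mode (placental
    versus yolk-only provisioning) shapes the evolution of male sexually
    selected traits and the rate of speciation on time-calibrated
    phylogenies.  Implements matrotrophy-index trait scoring from
    brood-level embryo mass data, maximum-likelihood and parsimony
    ancestral state reconstruction with stochastic character mapping for
    Mk models, Pagel-type correlated evolution of binary trait pairs with
    reversible-jump MCMC, stepping-stone marginal likelihoods and Bayes
    factors, binary- and multi-state speciation/extinction (BiSSE/MuSSE)
    models including additive two-trait main-effects parameterisations,
    nonparametric tip-rate (FiSSE-style) tests, and parametric-bootstrap
    calibration of trait-dependent diversification tests.  Ships
    simulators for birth-death and state-dependent trees, discrete trait
    histories, and brood-level mass data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    deSolve,
    Matrix,
    optparse,
    jsonlite
Config/testthat/edition: 3
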