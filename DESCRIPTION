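Package: flimbayes
Title: Bayesian Analysis of Time-Correlated Single Photon Counting
    Fluorescence Lifetime Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic photon bin-likelihoods for time-correlated single
    photon counting (TCSPC) fluorescence lifetime imaging (FLIM) decays
    under repetitive excitation, with the instrument response function
    modelled as a weighted mixture of truncated Gaussians. Provides maximum
    a posteriori estimation of mono- and multi-exponential decay
    parameters, Laplace-approximation model evidence and decay model
    selection, simultaneous instrument-response-and-decay estimation by
    simulated annealing, Poisson maximum-likelihood and least-squares
    direct-fitting baselines, a forward photon arrival-time simulator with
    excitation wrap-around, and Monte Carlo precision benchmarking for
    FRET studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
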