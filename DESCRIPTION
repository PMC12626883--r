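Package: msinfo
Title: Multiscale Stochastic Information Processing with Nonlinear
    Summation and Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and exact stationary analysis of multiscale
    stochastic input-processing-output networks in which units coupled by
    saturating (tanh) activation functions exchange information across
    separated timescales. Implements the two canonical activation schemes
    (nonlinear summation and nonlinear integration), random interaction
    ensembles with stability control, Euler-Maruyama and
    exponential-splitting Langevin integrators, exact conditional-Gaussian
    factorizations of the stationary density in the fast- and
    slow-processing limits (including the Gaussian-smoothed tanh special
    function evaluated by a stabilized alternating series), exact sampling
    schemes, nonparametric input-output mutual-information estimators,
    Sarle's bimodality coefficient, and figure-level sweep drivers over
    random-matrix ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
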