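Package: dyndisc
Title: Dynamical Discrimination of Stimuli from Single-Trial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recovers stimulus and context information from single scalar
    biological time series (membrane potential or transmembrane current) by
    time-delay dimensionality expansion, genetic-algorithm-driven sparse
    identification of nonlinear dynamics (SINDy), and ensemble random-forest
    decoding on the fitted ODE coefficient matrices. Includes linear stability
    analysis of the fitted equations, tuning-curve and reliability summaries,
    baseline decoders (deflection, occupancy maximum-likelihood, state-variable),
    and a synthetic benchmark in which Lorenz-system trajectories spanning a Hopf
    bifurcation drive Hodgkin-Huxley and Poisson-synapse point-neuron encoders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    ranger,
    deSolve,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
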