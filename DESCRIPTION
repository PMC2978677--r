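Package: bouton
Title: Stochastic Simulation of Vesicular Release at Hippocampal Presynaptic Boutons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Spatially explicit stochastic modelling of calcium-triggered
    neurotransmitter release at small CA3-CA1 presynaptic boutons. Includes
    Markov-chain gating of voltage-dependent calcium channels, particle-based
    reaction-diffusion of calcium with the mobile buffer calbindin-D28k and
    plasma-membrane calcium pumps, a dual calcium-sensor release scheme with a
    readily-releasable pool and zone-wide refractory coupling, protocol
    runners for action-potential trains and sensor knock-out variants, and an
    analysis layer for release histograms, multi-exponential decay fits,
    release probabilities, facilitation and calcium dose-response
    cooperativity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    deSolve,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
SystemRequirements: C++17
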