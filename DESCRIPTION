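Package: fluxscape
Title: Potential and Flux Landscapes of Stochastic Boolean Gene Networks
Version: 1.0.0
Authors@R:
    person("Daniel", "Kovacs", email = "dkovacs.dev@gmail.com",
           role = c("aut", "cre"))
Description: Builds the exact state-space Markov chain of a stochastic Boolean
    gene regulatory network, solves the master equation for transient and
    steady-state probabilities, and decomposes the non-equilibrium dynamics
    into a detailed-balance part and an irreversible curl-flux part. The
    steady state yields the potential landscape U = -ln(P) and its robustness
    ratio; the flux part is peeled into directed probability-flux loops that
    form the flux landscape of a limit-cycle oscillator. Also provides the
    steady-state entropy production rate, stochastic trajectory simulation
    with autocorrelation/power-spectrum analysis of oscillations, and a
    global sensitivity analysis (edge-deletion total evaluation score and
    backbone extraction). Ships the ten-node fission yeast cell-cycle network
    as the canonical example.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
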