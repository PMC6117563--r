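Package: scgate
Title: Aggregated Markov Models of NMDA Receptor Gating with Missed-Event Likelihood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic analysis of single ion-channel recordings with
    aggregated continuous-time Markov models, built around structurally motivated
    tetrameric NMDA receptor gating schemes. Provides declarative mechanism
    definitions with equality and microscopic-reversibility constraints
    (minimum-spanning-tree construction), assembly and spectral analysis of the
    transition-rate (Q) matrix, exact and asymptotic missed-event-corrected
    dwell-time densities and log-likelihood, maximum-likelihood fitting of dwell
    sequences on the log-rate scale with QR constraint reduction,
    profile-likelihood intervals, a seeded stochastic single-channel simulator,
    classical dwell-time statistics (resolution imposition, exponential-mixture
    fitting, critical shut time, burst segmentation), and deterministic
    macroscopic and synaptic current simulation and least-squares fitting under
    concentration-jump protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
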