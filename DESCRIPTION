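Package: munoise
Title: Motor Unit Pool Simulation of Force Variability in Human Tibialis Anterior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates isometric force production and its variability ("motor
    noise") from a population of motor units of the human tibialis anterior.
    A 200-unit pool converts a common effective synaptic input into stochastic
    spike trains (recruitment by the size principle plus rate coding with
    saturation of low-threshold units), turns spike trains into motor unit
    activation through a calcium-kinetics / cross-bridge cascade with sag and
    yield, and drives Hill-type musculotendon mechanics with a series-elastic
    element. Includes the classical twitch-summation pool of Fuglevand,
    Winograd and Enoka and a second-order signal-dependent-noise filter as
    reference models, together with the simulation protocols and statistics
    (activation-frequency and fusion curves, ramp-and-hold population trials,
    detrended SD/CoV of force, power spectra, recruitment pattern statistics
    and a sensitivity suite) used to quantify how much force variability motor
    unit properties can generate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
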