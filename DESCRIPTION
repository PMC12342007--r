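Package: tfsde
Title: Neural-Network-Encoded Transcription Factor Circuits as Stochastic
    Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and optimizes gene regulatory circuits in which small
    per-gene neural networks map transcription factor abundances to mRNA
    transcription rates inside a chemical-Langevin stochastic differential
    equation.  Includes a circadian tracking objective with an erratically
    switching external light signal, growing-horizon gradient training with
    pathwise (frozen-noise) derivatives through the integrator, daily
    crossing-time deviation analytics with ensemble percentile summaries,
    input-output surface grids for trained networks, and repressilator-style
    Hill-rule fixtures for testing every component without long optimization
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
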