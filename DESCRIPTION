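Package: parspace
Title: Stochastic Models and Statistics for ParA-Mediated Plasmid Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantification tools for parABC-mediated plasmid
    partitioning over the bacterial nucleoid. Provides the closed-form
    steady-state solution of a one-dimensional ParA-ATP reaction-diffusion
    gradient with plasmid flux balance, exact Gillespie lattice simulators for
    a diffusion/immobilization model and a directed-motion ParA polymer model
    (including perturbed-nucleoid variants), mean-square-displacement and
    weighted subdiffusion fitting for focus trajectories, segregation-event
    detection with a resampling test, nucleoid-relative positioning and
    asymmetry statistics, first-harmonic nucleoid-shape scoring, Pearson and
    Manders colocalization, and seed-deterministic synthetic data generators
    (fractional Brownian motion tracks and two-channel cell intensity stacks)
    so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
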