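Package: waveclock
Title: Waveform Distortion, Temperature Compensation, and Entrainment in
    Circadian Oscillator Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how waveform distortion of gene-activity
    rhythms relates to temperature compensation and entrainment of circadian
    clocks. Implements the three-variable Goodwin negative-feedback oscillator
    (unforced, light-forced, and Arrhenius temperature-scaled), generalized
    harmonic analysis of periodic time series, the non-sinusoidal power (NS)
    waveform index and the associated analytic period formula, a second-order
    renormalization-group solution of the Goodwin limit cycle with parameter
    sensitivities, randomized temperature-compensation parameter sweeps,
    Arnold-tongue entrainment analysis with an analytic synchronization bound,
    and a reanalysis pipeline for noisy bioluminescence-reporter-style
    recordings with synthetic data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    deSolve,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
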