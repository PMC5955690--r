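Package: oscmotor
Title: Oscillatory EEG Analysis of Proactive Motor Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sensorimotor and prefrontal
    EEG oscillations in a cued go-nogo-change task. Generates the experimental
    design and synthetic 64-channel EEG with known injected oscillatory
    structure (condition-dependent mu and beta amplitude envelopes, controllable
    alpha-band phase coupling, pink-noise background), preprocesses raw records
    (re-referencing, filtering, epoching, amplitude-based artifact rejection),
    applies a spherical-spline surface Laplacian (current source density)
    transform, computes Morlet-wavelet time-frequency power with baseline
    normalization and region-of-interest aggregation, estimates alpha-band
    phase-locking value connectivity, and runs the associated inferential
    layer: binned paired t-tests with false-discovery-rate correction,
    repeated-measures ANOVA with Greenhouse-Geisser correction, and Wilcoxon
    signed-rank contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
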