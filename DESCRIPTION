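Package: vestephys
Title: Whole-Cell Electrophysiology Analysis of Vestibular Hair Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings from
    vestibular type I and type II hair cells, together with a conductance-based
    simulator of such cells. Implements conductance-voltage (Boltzmann)
    fitting of tail, peak and steady-state currents, activation and
    bi-exponential inactivation kinetics with an adjusted-R-squared
    model-selection rule, A-type current classification, passive membrane
    properties (resting potential, input resistance, membrane time constant,
    capacitance from clamp transients), electrical resonance (damped-sinusoid
    fits and quality factor), pharmacological subtraction of drug-sensitive
    currents, and a group-comparison dispatcher with Hedge's g effect sizes.
    The simulator generates voltage-clamp and current-clamp recordings from
    genotype/zone/cell-type presets so every analysis stage can be validated
    on data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    car
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
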