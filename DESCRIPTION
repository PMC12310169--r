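Package: magstim
Title: Magnetostimulation Threshold Simulation and Strength-Duration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation pipeline for peripheral nerve
    magnetostimulation (PNS) threshold experiments with kilohertz-range
    sinusoidal magnetic fields. Provides a filamentary-loop magnetostatic model
    of a layered solenoid (field efficiency in uT/A), a series resonant-circuit
    model with exponential ramp-up pulse shaping and current-waveform fitting,
    psychometric (logistic) threshold estimation with an adaptive titration
    protocol, censoring-aware Gaussian population averaging, hyperbolic
    strength-duration curve (rheobase/chronaxie) fitting with IEC effective
    stimulus duration, pulse-duration threshold rescaling, and a synthetic
    cohort generator so the full analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
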