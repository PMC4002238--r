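Package: diastkin
Title: Kinematic Modelling of Diastolic Filling and Isovolumic Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward models, closed-form solutions and Levenberg-Marquardt
    inversion for two kinematic models of left-ventricular diastole: the
    parametrized diastolic filling (PDF) damped-oscillator model of the
    transmitral Doppler E-wave and the Chung model of isovolumic pressure
    decay, together with Weiss and logistic relaxation time-constants,
    pressure phase-plane utilities, Savitzky-Golay signal preparation,
    per-beat force computation (terminal force of isovolumic relaxation,
    initial force of early rapid filling), beats-within-subjects linear
    regression of the force-continuity relation, and a synthetic cohort
    generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
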