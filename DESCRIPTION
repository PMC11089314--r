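Package: fontansim
Title: Patient-Specific Closed-Loop 1-D/0-D Modelling of the Fontan Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow in the Fontan (total
    cavopulmonary connection) circulation with a closed-loop multiscale
    model: a univentricular heart built from time-varying elastance
    chambers and dynamic Bernoulli valves, one-dimensional pulse-wave
    solvers for the aorta and the cavopulmonary connection, and lumped
    (Windkessel) compartments for the upper body, lower body and lungs.
    Includes the open-loop calibration submodels, Ohmic resistance
    estimation helpers, intervention scenarios (pulmonary vasodilation and
    atrial fenestration), waveform error metrics, and cardiovascular index
    computation, together with a built-in patient parameter fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
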