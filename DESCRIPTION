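Package: glucodyn
Title: Mechanistic Modelling of Glucose-Accessibility-Limited Tumour Cell
    Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and calibrates a coupled ordinary-differential-equation
    model of breast-cancer-cell proliferation and death in culture, in which a
    glucose-uptake inhibitor (Cytochalasin B acting on GLUT1) limits the
    glucose concentration accessible to the cells through a dose-dependent
    inhibition constant. Provides forward simulation of live- and dead-cell
    confluence time courses, a synthetic-data generator emulating multi-well
    confluence experiments, a staged global/local nonlinear least-squares
    calibration workflow with confidence intervals, prediction from initial
    conditions alone, Lin's concordance correlation matching of accessible
    glucose levels, error metrics, and a benchmarking harness comparing the
    mechanistic predictor with standard machine-learning regressors under
    leakage-safe well-level train/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    rpart,
    ranger,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
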