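Package: moveholdlab
Title: Separable Analysis of Moving and Holding Control in Planar Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies resting postural force biases measured on a planar
    robotic manipulandum, reaching kinematics and responses to pulse and
    release perturbations, and the interaction statistics that test whether
    resting biases intrude on movement versus holding. Includes estimation of
    position-wise resting force-bias fields with scalar-potential (isocline)
    reconstruction, velocity-threshold event detection with the standard
    settling and stabilization rules, extreme-instance contrasts, per-subject
    sensitivity regressions, a Response Asymmetry Index, and a synthetic
    cohort simulator (point-mass arm with a gated posture controller) with
    full ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
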