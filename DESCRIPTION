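Package: pitchadapt
Title: Simulation and Analysis of Pitch-Altered Auditory Feedback Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing sensorimotor adaptation
    experiments with pitch-altered auditory feedback. Generates synthetic
    270-trial vocal sessions (baseline/ramp/hold/washout) with drifting
    speakers and parametric opposing or following responses, normalizes
    per-trial voice F0 against a cubic-polynomial reference fitted to
    baseline and late-washout trials, measures own-voice F0
    just-noticeable differences with a multi-QUEST Bayesian staircase and
    a d-prime based psychometric refit, and computes the adaptation and
    after-effect summary statistics of such studies, end to end on
    simulated speakers and simulated observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
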