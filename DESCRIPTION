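Package: lymphmm
Title: Hidden Markov Modelling of Lymphatic Metastatic Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a discrete-time hidden Markov model of metastatic spread
    through cervical lymph node levels (LNLs I-IV) in oral tongue squamous
    cell carcinoma. True per-level involvement is a hidden, monotonically
    progressing binary state on a directed lymphatic drainage graph;
    imaging diagnoses are noisy observations with fixed sensitivity and
    specificity. Per-arc spread probabilities and a stage-dependent
    binomial time prior are learned from cohorts of per-level diagnoses by
    Markov chain Monte Carlo, and the fitted model predicts the risk of
    occult (microscopic) involvement of each level given a patient's
    observed diagnosis pattern and T-stage. Includes the one-timestep
    Bayesian-network comparison model, synthetic cohort simulation,
    threefold cross-validation and predicted-risk versus prevalence
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
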