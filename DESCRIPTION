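Package: speechscreen
Title: Speech-Based Screening for Mild Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("speechscreen", "developers", email = "dev@speechscreen.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for screening mild traumatic brain injury
    (mTBI) from read-speech recordings. Implements mel-frequency cepstral
    coefficient (MFCC) feature extraction built from the perceptual mel-scale
    equations, a bidirectional LSTM classifier with additive temporal
    attention trained by stochastic gradient descent with momentum and early
    stopping, particle swarm optimisation over discrete hyperparameter
    candidate sets, participant-level train/validation/test splitting with
    leakage guards, and confusion-matrix / ROC / AUROC evaluation. Ships a
    seeded source-filter synthetic speech generator so the full pipeline is
    testable without clinical audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
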