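Package: delibdecode
Title: Time-Resolved Decoding of Outcome Representations During
    Approach-Avoidance Deliberation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of action-outcome representations from MEG-like multichannel
    sensor data recorded during a risky approach-avoidance foraging task.
    Provides a task and sensor-data generator with known ground truth
    (outcome-evoked spatial patterns, alternating deliberation-period
    representations, eyeblink artifacts), preprocessing and epoching with
    artifact-based channel selection, per-time-bin lasso-regularised logistic
    outcome classifiers scored by balanced accuracy, decoding of
    deliberation-period representation probabilities, autocorrelation and
    dwell-time statistics of decoded state sequences with permuted-classifier
    null ensembles and cluster-level inference, and linear mixed-effects
    time-course analysis of condition and choice effects with cluster-level
    permutation correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    lme4,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
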