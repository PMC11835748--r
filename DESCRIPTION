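Package: statesync
Title: Brain-State Synchrony and Facial Affect Dynamics in Depression Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discriminating depression subtypes from naturalistic-stimulus
    recordings: Gaussian-observation hidden Markov models fitted to concatenated
    multi-subject ROI fMRI time series (EM with subject-boundary resets, AIC model
    selection, Viterbi decoding), a windowed inter-subject brain-state consistency
    statistic with between-group resampling and within-group surrogate-chain null
    models, state-dynamics summaries (fractional occupancy, dwell time, transition
    matrices) with max-statistic permutation FWE and a network-based statistic on
    transition probabilities, facial action-unit group statistics from
    OpenFace-format recordings (t-tests with FDR, pooled principal component,
    bootstrap bands), and the epoch-level brain-behaviour ANCOVA interaction.
    Includes a synthetic-cohort generator emulating the statistical structure the
    analyses assume, so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
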