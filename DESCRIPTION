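Package: ccwemu
Title: Clone-Censor-Weight Emulation of Anticoagulant Initiation Trials
Version: 0.1.0
Authors@R: person("ccwemu", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for emulating a target trial that compares dynamic oral
    anticoagulant initiation strategies ("initiate when the CHA2DS2-VASc
    score first reaches a threshold" versus "never initiate") in
    longitudinal claims-style cohorts of elderly patients with atrial
    fibrillation and cancer. Implements the cloning, artificial-censoring
    and inverse-probability-weighting estimator with discrete-time pooled
    logistic hazard models, cluster-robust variance, standardized survival
    curves and incidence rates, together with a confounded synthetic-cohort
    generator and a forced-regimen Monte Carlo oracle for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
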