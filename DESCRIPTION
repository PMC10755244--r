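Package: msmcvd
Title: Marginal Structural Models for Antidepressant Exposure and
    Cardiovascular Events in Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds person-period cohorts from claims-style longitudinal
    records (diagnoses, prescriptions, health check-ups), computes
    cumulative defined-daily-dose antidepressant exposure, adjudicates a
    composite major-adverse-cardiovascular-event (MACE) outcome, and
    estimates marginal structural discrete-time survival models with
    stabilized inverse-probability-of-treatment weights, including
    dose-response, weight-truncation and e-value sensitivity analyses.
    Ships a synthetic claims generator with treatment-confounder
    feedback and a counterfactual ground-truth oracle so the whole
    pipeline can be validated without access to restricted registry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    survival,
    sandwich,
    nnet,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
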