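Package: haebn
Title: Bayesian Network Analysis of Mortality Risk in Hospitalized
    Hereditary Angioedema Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete Bayesian-network modelling of in-hospital mortality
    risk for hereditary angioedema (ICD-10 D84.1) admissions. Provides an
    expert-specified directed acyclic graph over patient demographics,
    comorbidities and APR-DRG severity; Bayesian parameter estimation of
    conditional probability tables under a symmetric Dirichlet prior;
    exact inference by variable elimination with hard and soft (virtual)
    evidence, backed by a full-joint enumeration oracle; a conditional
    mortality-risk query battery (baseline risk, single-factor deltas,
    multi-factor scenarios); a stratified train/test validation stage
    with the standard eight-metric confusion panel and ROC/AUC; and a
    calibrated synthetic hospital-discharge cohort generator so the full
    pipeline runs without access to licensed inpatient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
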