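Package: stablerx
Title: Predicting Antidepressant Treatment Stability from Coded Clinical Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying whether a patient starting antidepressant
    treatment will reach a stable regimen, using only coded clinical data
    (diagnoses, procedures, prescriptions). Defines treatment segments and a
    four-rule stability outcome from longitudinal prescription records
    (prescription spacing, segment duration, medication possession ratio,
    maximum refill gap), featurizes pre-index patient histories into sparse
    code-count vectors plus demographics, trains a prediction-constrained
    supervised latent Dirichlet allocation topic model alongside logistic
    regression and extremely randomized tree baselines, and evaluates models
    with bootstrap AUROC confidence intervals, top-3 medication-ranking
    accuracy, and quartile forecasting of medication trials. Includes a
    synthetic electronic-health-record generator with known topic structure
    and known stability outcomes so the full pipeline is testable end to end
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    glmnet,
    ranger,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
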