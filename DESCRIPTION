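Package: incvalue
Title: Incremental Value of Risk Prediction Models via AUC, Average
    Precision, and Scaled Brier Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and compares the incremental value (IncV) of a new risk
    prediction model over an existing one using three accuracy measures: the
    area under the ROC curve (AUC), the average precision (AP, area under the
    precision-recall curve), and the scaled Brier score (sBrS). Provides
    analytic "true" values for binormal risk scores and for misspecified
    probit working models under a probit data-generating mechanism with an
    interaction (population working-model coefficients, intercept calibration
    to a target event rate, conditional score distributions by semi-analytic
    quadrature), the common-integrand decomposition of IncVs as weighted
    averages of the change in separation between event and non-event score
    distributions, nonparametric estimators of all three measures from
    individual-level samples, seeded synthetic-data generators, scenario
    sweeps with summaries, correlation and concordance of IncV metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
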