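Package: hetsurv
Title: Predictor Measurement Heterogeneity and Survival Model Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying how heterogeneity
    in a predictor's measurement between the validation and implementation
    setting of a time-to-event prediction model degrades out-of-sample
    performance. Generates cohorts from a Cox-exponential data-generating
    mechanism with administrative and random censoring, applies additive,
    multiplicative and random measurement-heterogeneity scenarios to a flagged
    predictor, fits exponential and Cox proportional-hazards models, evaluates
    horizon-specific performance (observed/expected ratio, cumulative-dynamic
    time-dependent AUC, Brier score and index of prediction accuracy, all with
    inverse-probability-of-censoring weighting and bootstrap confidence
    intervals), and orchestrates a seven-step quantitative prediction error
    analysis with marginalized report bands, tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
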