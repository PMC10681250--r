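Package: icbtri
Title: Dynamic Prediction of Reliable Improvement in Internet-Delivered CBT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamic outcome-prediction pipeline for
    internet-delivered cognitive behavioural therapy (iCBT) cohorts
    monitored with PHQ-9 and GAD-7. Generates longitudinal synthetic
    client cohorts with informative dropout, labels reliable improvement
    with the Jacobson-Truax reliable change criterion under
    last-observation-carried-forward censoring, builds sequence and
    fixed-length featurizations, trains a many-to-one LSTM classifier
    alongside logistic regression, random forest, gradient boosting and
    exponential-moving-average benchmarks, and evaluates predictions at
    every review period with sensitivity-at-fixed-specificity operating
    points, cluster-bootstrap intervals, severity-band stratification,
    Kaplan-Meier time-to-improvement curves and trajectory-level error
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    ggplot2,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
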