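Package: remcurve
Title: Logistic Remission-Curve Modelling and Early Efficacy Prediction
    for Physiotherapy Pain Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models per-session visual analogue scale (VAS) pain
    trajectories of lumbar disc herniation patients under physical therapy
    as decreasing logistic remission curves with the upper asymptote
    anchored one minimal clinically significant difference (1.2 VAS
    points) above the first rating. Provides truncated-course refitting to
    predict the end-of-course pain score from the first m sessions, with
    effectiveness and remission-magnitude success rates scored by the
    1.2-point rule and compared by pooled-cell chi-square tests; a
    from-scratch least-squares gradient-boosting classifier with
    regression-tree base learners, shrinkage and split-gain feature
    importance; ROC/AUC evaluation with DeLong or bootstrap confidence
    intervals and the Youden-optimal operating point; and a synthetic
    cohort generator so the full analysis is reproducible without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
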