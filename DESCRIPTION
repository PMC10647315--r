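Package: lrtrend
Title: Longitudinal Radiomic Trend Analysis for Treatment Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal trend analysis of radiomic features extracted
    from daily in-room imaging (e.g. cone-beam CT) over a fractionated radiotherapy
    course. Per-patient feature series are z-score normalized with outlier bounding,
    reduced to per-feature least-squares trend statistics (slope, intercept, fit
    error and their sum, the longitudinal radiomic trend feature), screened by
    Mann-Whitney U tests and univariate logistic regression, and used to classify
    treatment responders versus non-responders with a random-forest model and an
    interpretable p-value-weighted statistical-weight model. A leave-one-out
    cross-validation suite over every treatment-length cutoff quantifies accuracy,
    AUC and a per-patient consistency index. A synthetic-cohort simulator with known
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    ranger,
    pROC,
    ggplot2,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
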