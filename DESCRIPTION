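Package: foresiin
Title: Interpretable Independent Recurrent Networks for Stroke Risk After Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts one-year ischemic stroke risk in atrial-fibrillation
    patients from irregular electronic-health-record time series. Implements
    the ForeSIIN architecture: one independent gated-recurrent-unit branch per
    clinical feature over a 24-month summarized sequence, combined additively
    so every prediction decomposes exactly into per-feature effects. Includes
    the accompanying protocol: monthly mean/mode summarization with an
    imputation-free -1 sentinel for missing values, stratified splitting with
    4:1 down-sampling, threshold policies (fixed, Youden, F1), bootstrap
    confidence intervals, survival evaluation (Harrell's c, Kaplan-Meier,
    log-rank, decision curves), CHA2DS2-VASc and ATRIA comparators, classic
    machine-learning benchmarks, and a synthetic cohort generator with planted
    ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    ranger,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
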