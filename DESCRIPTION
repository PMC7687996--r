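Package: hypoforecast
Title: Forecasting Hypotension Events from Minute-by-Minute ICU Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for forecasting the first hypotension
    event of an intensive-care stay from minute-by-minute vital signs.
    Includes a synthetic ICU cohort simulator (autocorrelated baselines,
    programmable decompensation, missing-data bursts, out-of-range
    artifacts), plausibility-bound cleaning and causal moving-average
    imputation, sliding-window hypotension event detection with gap
    merging, rolling multi-window feature engineering (summary statistics,
    discrete Fourier transform magnitudes, exponentially weighted moving
    averages), event-anchored labeling with a chronological train/validation
    split, risk modelling with four classifier families under subject-level
    cross-validation, event-aligned risk-score trajectories, a stacked
    second-stage alert model with a lockout policy and alarm-burden
    metrics, and lead-time-resolved discrimination and calibration
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ranger,
    xgboost,
    glmnet,
    class,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
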