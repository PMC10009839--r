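Package: shortcast
Title: Forecasting Drug Shortage Impact from Pharmacy Dispensing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting drug shortages at the interchangeable-group
    (IG) level from pharmacy dispensing records and public shortage reports.
    Cleans free-text shortage reports and resolves them against a pack-size
    catalog, computes a monthly shortage impact score per IG (the
    days-of-supply-weighted fraction of unavailable pack listings), engineers
    lagged demand, preference-concentration and therapeutic-class-neighbourhood
    features, fits per-IG gradient-boosted tree forecasters under blocked
    time-series cross-validation, and evaluates forecasts with MAE, four-class
    binning, Cohen's kappa and impactful-shortage detection. A seeded synthetic
    data generator emulates the statistical structure of pharmacy dispensing
    and shortage-report data so the full pipeline is testable without access
    to proprietary records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
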