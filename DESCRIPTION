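Package: neurocast
Title: Multi-Resolution ARIMA Forecasting of Cerebral Physiologic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how temporal resolution reduction affects
    ARIMA point and interval forecasts of multimodal neuromonitoring
    signals. Simulates seeded synthetic cohorts of arterial blood
    pressure, intracranial pressure and brain tissue oxygen waveforms;
    derives minute-by-minute mean pressures, pulse amplitude (AMP) and
    the cerebrovascular reactivity indices PRx, PAx, RAC and RAP from
    windowed Pearson correlations; reduces series over a ladder of
    resolutions from 1 minute to 24 hours with explicit missing-data
    rules; fits ARIMA models by conditional-sum-of-squares with
    AIC-based order selection; and evaluates forecasts under one-step
    ahead, blocked and expanding-window time-series cross-validation
    with MAE, RMSE, R-squared and prediction-interval spread.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
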