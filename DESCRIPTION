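Package: workloadcast
Title: Forecasting Athlete Workload Indicators from Wearable Session Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for monitoring training and match workload of team-sport
    athletes from per-session wearable-sensor summaries. Provides a validated
    tabular data model for session-level key performance indicators (total
    distance, maximal speed, maximal metabolic power, accumulated acceleration
    load, jumps, changes of direction), a calibrated synthetic panel generator
    with position profiles, match effects and serial correlation, classical
    univariate baselines (moving average, exponential smoothing, ARIMA), a
    multi-target recurrent (LSTM) forecaster with player embeddings and an
    exogenous session-type channel, Monte-Carlo dropout prediction intervals,
    rolling holdout evaluation (RMSE, MAPE, interval coverage), gradient-based
    feature attribution, and a deterministic natural-language report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
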