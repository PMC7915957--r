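Package: biogasdlm
Title: Self-Learning Distributed-Lag Modelling of Biogas Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven simulation of hourly biogas production in full-scale
    anaerobic digesters from the history of solid (and optionally liquid)
    substrate feeding. Implements a distributed-lag linear regression fitted
    by ordinary least squares on a rolling training window, multi-step
    simulation of production from planned feeding schedules, rolling-origin
    accuracy evaluation (MAPE, MAE, RMSE) over a grid of model settings, and
    coefficient-based analysis of gas-formation kinetics including the
    cumulative specific biogas yield. A calibrated synthetic plant-data
    generator provides reproducible hourly feeding/production series with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
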