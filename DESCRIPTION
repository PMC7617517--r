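Package: luxmetrics
Title: Import, Preprocessing and Metrics for Wearable Light-Exposure Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for personal light dosimetry with wearable light loggers.
    Imports device CSV exports through a registry of declarative per-device
    dialects, regularises irregular time series (implicit-gap discovery and
    filling, aggregation to coarser epochs, time-of-day and date filtering,
    sleep-diary interval joining), and computes 61 exposure metrics across
    17 families: threshold-based durations, timings and pulses, brightest
    and darkest periods, centroid and midpoint of cumulative exposure,
    interdaily stability and intradaily variability, exponential smoothing,
    disparity index, Barroso lighting metrics, modelled non-visual direct
    and circadian responses, and cumulative dose. Includes a ground-truthed
    synthetic data generator, a day-faceted exposure plot, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
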