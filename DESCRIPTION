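Package: ssrlag
Title: Distributed-Lag Additive Models for the Secondary Sex Ratio at Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ambient temperature around the time of
    conception shapes the secondary sex ratio at birth in monthly aggregated
    historical birth registers. Estimates conception months from birth months
    (15th of the month minus 280 days), assembles lagged monthly temperature
    covariates for lags -9..+9 around conception, and fits penalized-spline
    binomial logistic additive models with automatic smoothness selection,
    including an Almon polynomial distributed-lag sub-model whose per-lag
    coefficients are recovered with pointwise confidence intervals. Also
    provides percentile-based thermal classification of monthly temperature
    series (11 ordered classes from the 5th-95th percentile thresholds),
    decadal trend tests, and a seeded synthetic-data generator with known
    ground truth for recovery and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    utils
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
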