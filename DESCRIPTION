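Package: sampsizesim
Title: Simulation-Based Sample Size Calculations for Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing the development sample size of clinical risk
    prediction models with binary (and time-to-event) outcomes. Implements the
    closed-form Riley/van Smeden criteria based on the target expected
    calibration slope (shrinkage) and the target expected mean absolute
    prediction error (MAPE), calibration of a normally distributed linear
    predictor to an anticipated outcome prevalence and c-statistic (including
    the Cox-Snell R-squared mapping), Monte Carlo evaluation of the
    distribution of the calibration slope, c-statistic and MAPE at a given
    development sample size, and a simulation-based bisection search for the
    sample size that attains a target expected calibration slope or MAPE. An
    exponential time-to-event data-generating mechanism with administrative
    censoring and Harrell's c-index is included for survival outcomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    pracma,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
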