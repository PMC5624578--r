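Package: arclim
Title: Confidence Limits for Indexes Derived from Autoregressive Models of
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates confidence limits and performs single-recording
    significance tests for descriptive indexes derived from autoregressive
    (AR) models of time series, with heart-rate-variability analysis as the
    motivating application.  An AR model is identified by least squares from
    one recording; the sampling distribution of the model parameters is then
    reproduced either by Monte Carlo sampling of their estimated Gaussian
    distribution or by bootstrap resampling of the model residuals, and any
    index computed from the parameters (low-frequency peak frequency, LF/HF
    power ratio via spectral decomposition, information storage) inherits an
    empirical sampling distribution from which percentile confidence limits
    and two-recording difference tests are read.  Includes pole-based AR
    simulators (linear, quadratic-nonlinear, threshold-switching,
    trend-contaminated), a multiple-realizations gold standard, and drivers
    for simulation studies and cohort analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
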