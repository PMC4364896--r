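Package: pulsepop
Title: Consumer-Resource Dynamics Driven by Climate-Predicted Resource Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting outbreaks of seed-eating consumers (invasive
    house mice in New Zealand beech forest as the motivating system) from
    climate-driven resource pulses. Annual seedfall is predicted from the
    change in mean summer temperature between the two preceding years (the
    delta-T mast model), and drives a mechanistic consumer-resource
    differential-equation model with pulsed seed input, exponential seed loss
    and a choice of functional responses (Holling I/II, Ivlev, uncapped).
    Includes RMSE-based model fitting with multi-start simplex optimisation,
    nonparametric bootstrap confidence intervals, AICc model comparison,
    long-horizon outbreak-threshold analysis (logistic versus linear
    dose-response of spring peak abundance and winter rate of increase on
    delta-T and seedfall), mast-year classification by standardized deviates,
    climate-scenario bias adjustment and mast-frequency statistics, and a
    synthetic-data generator emulating the statistical structure of the field
    system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
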