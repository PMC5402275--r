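Package: ivhsignals
Title: Time-Series Analysis of Neonatal Blood Pressure and Airflow for
    Intraventricular Haemorrhage Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predictive monitoring of intraventricular
    haemorrhage (IVH) in preterm infants from continuous arterial blood
    pressure and ventilator airflow waveforms. Implements non-linear
    baseline detrending of the pressure signal, beat and breath
    detection, sliding-window signal quality control with outlier
    removal, detrended fluctuation analysis (DFA) over short (4-15) and
    long (15-50 beat) scales, and logistic-regression risk models
    evaluated with ROC curves, DeLong confidence intervals and
    comparisons, likelihood ratios at fixed specificity, and
    leave-one-out cross-validation. A synthetic-data module generates
    fractional Gaussian noise, pulsatile pressure and airflow waveforms,
    artifact injection, and whole cohorts, so that every pipeline stage
    is testable without patient recordings.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
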