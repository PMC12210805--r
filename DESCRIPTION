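Package: thresholdval
Title: Sample Size for External Validation of Prediction Models Using
    Threshold-Based Performance Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning toolkit for external validation studies of clinical
    prediction models with a classification threshold. Computes the minimum
    sample size required to estimate accuracy, specificity, sensitivity
    (recall), positive and negative predictive value (precision, NPV) and the
    F1-score with a target confidence-interval width, in closed form where the
    measure is a simple proportion and by iterative search for the F1-score
    using its precision-recall covariance. Also implements the four
    established validation criteria (observed/expected ratio, calibration
    slope via Fisher information, c-statistic via Newcombe's standard error,
    and standardised net benefit), Agresti-Coull adjusted intervals with an
    iterative sample-size search, and a time-to-event extension based on
    jackknife pseudo-observations from the Kaplan-Meier estimator with a
    simulation engine for expected confidence-interval widths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
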