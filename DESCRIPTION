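Package: cgmforecast
Title: Interdependent Learning Frameworks for Personalised Blood Glucose Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and compares four learning frameworks for personalised
    short-horizon blood glucose forecasting from continuous glucose monitoring
    (CGM) series: independent learning (IL), adversarial learning (AL),
    collaborative learning (CL), and adversarial-collaborative learning (ACL).
    All four share one deployable sequence-to-sequence primary regressor; the
    interdependent variants add an auxiliary discriminator (adversarial
    supervision within the prediction horizon) and/or an auxiliary regressor
    (collaborative supervision via the post-horizon window, backpropagated into
    the primary regressor). Includes an Ohio-style CGM simulator, leak-free
    imputation and sliding-window reframing, mathematical (RMSE, MAE, MAPE, r2)
    and clinical (surveillance-error banding, adverse-event MCC) evaluation,
    and Friedman/Nemenyi/Holm critical-difference model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
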