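Package: pigaid
Title: Closed-Loop Insulin Delivery Simulation in Virtual Diabetic Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minute-resolution glucose-insulin simulation of insulin-deficient
    pigs under full closed-loop control without meal announcements. Provides an
    exponential insulin activity/insulin-on-board model with pharmacokinetic
    curve fitting, a calibrated virtual-pig glucose simulator with a noisy
    5-minute continuous glucose monitor, two dosing controllers (an oref1-style
    multi-forecast microbolus controller and a Loop-style model-predictive
    temporary-basal controller), the daily meal-challenge protocol with
    hypoglycemia rescue rules, and the time-in-range glycemic metrics used to
    score the algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    rlang,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
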