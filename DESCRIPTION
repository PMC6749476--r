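Package: ecgm
Title: Correcting Continuous Glucose Monitor Error During Exercise with
    Wearable Signals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies and corrects the accuracy loss of continuous glucose
    monitors (CGM) during aerobic exercise using signals from consumer
    wearables. Implements a zero-intercept linear model of the CGM error
    against baseline-removed wearable signals, a four-criterion backwards
    input-elimination protocol, leave-nine-out cross-validation of the
    corrected sensor trace, MARD and glycemic-variability metrics, Clarke and
    Parkes (consensus) error-grid analysis and the ISO 15197:2013 acceptance
    region, together with a synthetic exercise-trial generator emulating the
    data structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
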