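Package: emaccel
Title: Linking Parent-Reported Momentary Surveys of Child Activity to
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studies that pair signal-contingent ecological
    momentary assessment (EMA) surveys of a child's physical activity and
    sedentary behavior, answered by a parent, with hip-worn accelerometer
    data from the child. Implements 15-second epoch reintegration to
    counts per minute, Evenson cutpoint classification into sedentary
    time, light, and moderate-to-vigorous physical activity, detection of
    nonwear as runs of more than 60 consecutive zero-count minutes,
    wear-time validity filtering, hour-resolution matching of each
    completed survey to its accelerometer pre-period, standardization of
    outcomes to minutes per worn hour, and marginal (GEE-type) linear
    models with an independence working correlation and Huber-White
    cluster-robust variance, including Wald interaction tests and stratum
    estimates. A synthetic-data generator produces dyad cohorts, epoch
    count streams with known minute-level ground truth, EMA prompt
    schedules, and imperfect parent reports, so the full pipeline is
    testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
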