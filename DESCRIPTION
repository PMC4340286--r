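Package: setupmargins
Title: Setup-Error Decomposition and CTV-PTV Margins for Image-Guided
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort analysis of daily image-guidance couch shifts in
    external-beam radiotherapy: decomposition of setup errors into group
    mean (M), systematic (inter-patient, Sigma) and random (inter-fraction,
    sigma) components, van Herk CTV-to-PTV margin computation
    (2.5*Sigma + 0.7*sigma), paired comparison of shifts obtained against
    two reference imaging modalities (CT vs MRI), paired structure-volume
    and dose-metric comparison statistics, and a synthetic-cohort generator
    for parameter-recovery and Monte-Carlo coverage validation. Ships the
    per-patient summary tables of a ten-patient open-MRI prostate
    simulation cohort as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
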