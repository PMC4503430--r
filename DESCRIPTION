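Package: riskviz
Title: Color-Chart Visualization of Additive Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for presenting additive risk prediction models (logistic
    regression and Cox proportional hazards) as color-bar model charts and
    patient-specific contribution charts, as an alternative to nomograms.
    Per-term contributions to the linear predictor are shifted against a
    configurable zero reference (observed training minimum, predictor means,
    or a custom reference patient), converted to risks through the model
    link, and rendered as backend-independent chart scenes exportable to SVG
    and PNG. Points-based clinical score systems (per-predictor point bins
    plus a score-to-risk conversion table) are supported as first-class
    models, including the Framingham intermittent-claudication score system
    as a bundled fixture. Includes a synthetic training-data generator, JSON
    model/patient/score-system readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    grid,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
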