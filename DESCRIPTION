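Package: silfat
Title: Body Composition from Single Lateral Silhouette Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation of total and abdominal (L2-5) fat mass from a single
    standing lateral photograph, re-implemented as an open, testable pipeline.
    Provides silhouette conditioning (binarization, largest-component
    extraction, hole filling, acquisition quality control), anatomical
    landmark detection on binary masks, virtual-frame construction and
    pixel-occupancy features, gender-specific regression models trained
    against DXA-style reference values, the full method-agreement statistics
    battery (Lin's concordance correlation, Bland-Altman limits of agreement,
    technical error of measurement, pure and percent error, linearity tests),
    and a parametric synthetic silhouette cohort generator so that every
    stage can be exercised end to end without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
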