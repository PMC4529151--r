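Package: rpcsvoct
Title: Speckle-Variance OCT Angiography and Radial Peripapillary
    Capillary Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Label-free angiography of the radial peripapillary
    capillaries (RPCs) by speckle-variance optical coherence tomography
    (svOCT), together with a fully synthetic phantom so every stage can
    be validated against known ground truth. Provides closed-form beam
    optics and reduced-eye scan calibration, a seeded generator of
    parallel capillary networks rendered both as repeat-frame OCT
    speckle volumes and as histology-style en-face images, speckle
    variance computation with percentile thresholding and streak
    removal, shortest-path retinal layer segmentation with RNFL
    thickness measurement, capillary density / inter-capillary distance
    / diameter morphometry, and linear mixed-effects analyses of the
    resulting study tables (eye nested in subject).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
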