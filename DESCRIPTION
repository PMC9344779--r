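Package: cytodetect
Title: Nucleus Detection in Papanicolaou-Stained Oral Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cell nuclei of blue-stained (basal-lineage)
    cells in Papanicolaou-stained liquid-based oral cytology images.
    Implements a sliding-window patch pipeline (96x96 tiling, a
    nucleus-coverage labelling rule restricted to blue-lineage cells,
    balanced dataset assembly with a stratified 3:1 split, a configurable
    convolutional patch classifier with a configuration-grid runner, and
    red/yellow probability overlays) alongside a trainable instance
    segmentation backend and a classical hue-threshold reference detector.
    A synthetic cytology scene generator with exact per-instance ground
    truth makes every stage testable end to end, and a four-criterion
    matched-region evaluation protocol (detection count, background
    false-detection fraction, average undetected regions per nucleus,
    average detected regions per nucleus) compares detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
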