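Package: laurdanGP
Title: Laurdan Generalized Polarization Imaging of Red Blood Cell
    Membrane Fluidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric Laurdan imaging of red
    blood cell (RBC) membranes. Converts dual-channel (blue/green)
    confocal images into per-pixel generalized polarization (GP) maps,
    segments RBC from background and debris, isolates liquid-crystalline
    (LC) membrane domains by reference-stack percentile thresholding,
    measures per-domain morphometrics (area, perimeter, Feret diameter,
    circularity) with ImageJ-compatible estimators, and compares groups
    with one-way ANOVA and Holm-adjusted post-hoc tests. Includes a
    synthetic dual-channel image generator with known ground truth so
    the whole pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    rlang,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
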