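Package: somascope
Title: Stereological Soma Counting and Morphometry in 3D Fluorescence
    Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for stereological (full 3D) detection, counting and
    morphometry of fluorescently labelled neuronal somas in anisotropic
    image stacks. Provides a synthetic phantom generator with known
    ground truth, foreground extraction by binarization and erosion,
    sparse L1 ball-superposition soma localization with block-wise
    processing for large volumes, planar (z-projection) counting for
    comparison, per-soma morphometry (principal-axis radii, surface
    area, volume, brightness), per-region counts and densities against
    an integer label volume, optimal detection-to-truth matching with
    recall and precision, and the paired statistics used to compare 3D
    with planar counts. Includes SWC and multi-page TIFF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
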