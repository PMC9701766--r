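Package: spinereg
Title: Rigid Registration of CT-Based Lumbar Vertebra Meshes to Biplanar
    Standing Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring the standing sagittal alignment (lumbar
    lordosis) of biplanar radiographs onto supine CT-derived 3D lumbar spine
    models. Provides per-vertebra rigid 2D-3D registration of triangle meshes
    to target contours on calibrated frontal and sagittal projection views,
    silhouette contour projection in a simulated biplanar X-ray environment,
    gradient-attracted contour snapping, postregistrational midsagittal
    sections with intersegmental and lumbar lordosis angle measurement, and
    agreement metrics (Dice similarity index on voxelized meshes, Metro-style
    mean surface distance, Hausdorff distance, and two-way mixed-effects
    absolute-agreement intraclass correlation coefficients). A parametric
    synthetic spine generator produces supine/standing pose pairs with known
    ground truth so the whole pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
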