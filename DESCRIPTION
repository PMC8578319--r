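Package: ventmech
Title: Ventricular Wall Mechanics and Periventricular Lesion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasistatic plane-strain finite-element analysis of lateral
    ventricle pressurization with a one-term Ogden hyperelastic model,
    extraction of ependymal-cell stretch mechanomarkers (tangential tension,
    normal compression, maximum principal strain) along the ventricular wall
    from Laplacian direction fields, horn-radius estimation by a three-point
    circle fit, threshold-based white matter hyperintensity segmentation with
    CSF-adjacency pruning, and the statistical relationships among horn
    radius, ependymal stretch, and lesion burden. Includes a parametric
    synthetic subject generator (ventricle geometry, FLAIR-like images with
    planted lesions) so the full pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    interp,
    sp,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
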