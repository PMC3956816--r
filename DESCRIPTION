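Package: ctxa
Title: DXA-Equivalent Hip Densitometry from Quantitative CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts calibrated 3D quantitative CT (QCT) volumes of the
    proximal femur into DXA-like 2D areal bone mineral density projections
    and measures the standard hip regions of interest (femoral neck,
    trochanter, intertrochanter, total hip), including cortical and
    trabecular compartments separated by a volumetric density threshold.
    Includes in-scan K2HPO4 rod-phantom calibration with quality-assurance
    checks, an adaptive bone segmentation algorithm, standard-pose
    reorientation, a constructive-solid-geometry digital femur phantom with
    analytic ground truth, and the densitometry statistics used to validate
    such systems (long-term RMS-SD precision, interobserver comparison,
    cross-device regression with standard error of the estimate, Welch
    t-tests, Anderson-Darling normality testing).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    nortest,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
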