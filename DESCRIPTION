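Package: ctfootprint
Title: Muscle-Attachment Footprint Morphometry from CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bone and radiopaque-paint surfaces from CT-like
    volumes by Hounsfield-unit thresholding and isosurface extraction,
    builds coherent per-specimen bone models by rigid (landmark + ICP)
    registration, merging and smoothing, and measures muscle-attachment
    footprints on the bone surface: area, centroid, best-fit plane and
    breakthrough point, plus femoral morphometrics (mechanical axis,
    transepicondylar axis, head and shaft diameter) in an ISB anatomical
    frame.  Cohort tables report mean, population standard deviation and
    coefficient of variation.  A synthetic-specimen generator provides
    phantom bones, paint patches with analytic ground truth and voxelized
    CT volumes so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
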