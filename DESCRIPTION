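Package: arfusion
Title: SPECT/CT to Intraoperative CT Fusion with Augmented-Reality
    Overlay Accuracy Metrics on a Digital Pelvic Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-twin workflow for preoperative SPECT/CT to
    intraoperative CT fusion aimed at pelvic sentinel-lymph-node (SLN)
    targeting. Generates a synthetic pelvic phantom (radiopaque pelvis,
    iliac-like vessel tree, two fillable SLN spheres of 8 and 15 mm, and
    a fiducial calibration board), simulates CT-like and SPECT-like
    acquisitions (Gaussian point-spread blur, Poisson counting noise)
    under seeded rigid misalignments, segments the target structures,
    aligns the sessions by closed-form fiducial registration and
    mutual-information rigid registration (4x4 homogeneous matrices,
    trilinear resampling), renders augmented-reality and ground-truth
    2D masks through a pinhole camera, and scores the overlay with the
    normalized barycenter distance d(b1,b2)/r and the coverage rate
    of the visible surface by the augmented-reality surface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'arfusion-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'transforms.R'
    'volume.R'
    'camera.R'
    'io.R'
    'metrics.R'
    'registration.R'
    'segmentation.R'
    'phantom.R'
    'experiment.R'
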