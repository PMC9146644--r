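Package: prostasm
Title: Hybrid Deep-Initialised Active Shape Model Segmentation of the
    Prostate in 3D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines coarse volumetric prostate segmentations (for example the
    output of a 3D convolutional network) with a three-dimensional statistical
    shape and appearance model. Provides NIfTI volume handling with isotropic
    resampling, MRI preprocessing (log-domain polynomial bias-field correction
    and piecewise-linear landmark intensity standardisation), a point
    distribution model built from ellipsoid-guided ray-casting correspondences
    on alpha-shape surfaces, gray-level appearance profiles filtered with
    DBSCAN, the constrained iterative active shape model search, mesh-to-mask
    post-processing, volumetric evaluation metrics (Dice, 95th-percentile
    Hausdorff distance, relative volume difference), and a synthetic phantom
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    RANN,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
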