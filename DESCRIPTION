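Package: penna3d
Title: Muscle Fascicle Orientations from Freehand 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs 3D B-mode volumes from tracked 2D ultrasound frame
    stacks and estimates per-voxel muscle fascicle orientations by slice-wise
    multiscale vessel enhancement (Frangi) filtering followed by 3D Hessian
    eigenanalysis, a pruning cascade (intensity binarization, mask erosion,
    anisotropic length scaling, neighbour-count endpoint removal) and
    DCT-based penalized least-squares vector-field smoothing with support for
    missing voxels. Computes pennation angles against the aponeurosis
    principal axis, wire-phantom angle statistics and muscle volumes, and
    ships synthetic generators (wire phantom, two-compartment pennate muscle)
    with exact ground-truth direction fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    RNifti,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core.R'
    'directions.R'
    'filters.R'
    'io.R'
    'metrics.R'
    'penna3d-package.R'
    'pipeline.R'
    'recon.R'
    'smoothn.R'
    'synth.R'
    'vesselness.R'
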