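Package: limbscan
Title: Multi-View RGB-D Capture, Registration and Surface Reconstruction
    for Residual Limb Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a five-camera RGB-D
    photogrammetry pipeline for scanning convex limb-like objects such as
    plaster cast molds and residual limbs. Provides pinhole camera design
    mathematics (field-of-view extents, resolution, standoff distances),
    Kabsch rigid alignment and multi-camera extrinsic calibration from
    shared checkerboard corner sets, depth- and color-based segmentation
    with Otsu thresholding and morphological cleanup, RGB-D deprojection to
    point clouds, voxel downsampling, normal estimation, point-to-plane
    iterative closest point refinement with ordered pairwise fusion,
    implicit surface reconstruction to a watertight triangle mesh, and
    Dice/Hausdorff validation metrics with summary statistics. A synthetic
    scene simulator (parametric limb phantom, rig pose generator, analytic
    ray-cast renderer, checkerboard corner generator, depth-noise model)
    replaces the physical rig so the whole pipeline runs and is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
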