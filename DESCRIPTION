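Package: dermatrack
Title: Markerless Multi-View 3D Localization of Skin Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects blob-like skin features (moles, pigment spots) in
    multi-camera grayscale images with MSER and fast-Hessian detectors,
    matches them along rectified epipolar scan lines by descriptor SSD,
    triangulates matched features as the midpoint of the common
    perpendicular between back-projected rays (reporting the segment
    length as a per-feature triangulation error in millimetres), removes
    3D outliers by MSAC plane fitting, and estimates the analyzed skin
    area from a Delaunay triangulation of the inliers. Includes a fully
    ground-truthed synthetic camera-rig simulator for validation and a
    bright-marker benchmark against known 3D positions, aimed at
    markerless patient tracking in surgical navigation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
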