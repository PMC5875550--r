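Package: contourdose
Title: Geometric and Dosimetric Accuracy Analysis for Radiotherapy Contours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating the geometric accuracy of radiotherapy
    organ-at-risk segmentations to their dosimetric accuracy. Provides a
    voxel-structure data model on physical grids with contour rasterization
    and surface extraction; six geometric comparison metrics (Dice similarity
    coefficient, conformity index, centroid separation, mean and maximum
    distance-to-agreement, and the 95th-percentile Hausdorff distance);
    STAPLE expectation-maximization fusion of multi-observer contours into a
    probabilistic ground truth; mean-dose extraction from dose grids with
    dosimetric-accuracy and interobserver-variation statistics; a Pearson
    correlation study pipeline; and a synthetic cohort generator emulating
    parotid-like (unidirectional steep gradient) and larynx-like (opposing
    gradients) dose geometries for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
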