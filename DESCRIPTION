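Package: atlasforge
Title: Probabilistic Subcortical Atlas Construction and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating probabilistic brain atlases from
    multi-observer manual segmentations on a common template grid: voxel-wise
    label fusion by simple averaging, hemispheric reflection warps with
    third-order B-spline resampling of probability maps, probability-weighted
    volumetry and percent laterality indices, cumulative relative frequency
    (CRF) uncertainty curves, Dice and directed Hausdorff rater-reliability
    reports, and a synthetic phantom generator that reproduces the
    multi-observer, multi-template validation design end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
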