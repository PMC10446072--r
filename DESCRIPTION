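Package: pseudoislet3d
Title: Quantification of 3D Pseudoislet Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying multicellular pseudoislet aggregates in
    multi-channel 3D fluorescence microscopy z-stacks: background removal
    and intensity normalisation, 3D segmentation of nuclei and cells
    (thresholding, connected components, distance-transform watershed,
    blob detection), volumetric core/mantle partitioning of the spheroid,
    and object-based cell-ECM co-localization.  Ships presets that emulate
    the published analysis chains of four image-analysis platforms, a
    synthetic pseudoislet simulator with exact ground truth, and a
    benchmark harness reporting relative count changes against that truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
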