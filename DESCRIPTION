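Package: bonegrad
Title: Spatially Resolved Cortical Bone Morphometry and Structure-Function
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for quantifying radial and longitudinal gradients of
    cortical bone microstructure from grayscale micro-CT volumes and relating
    them to compressive mechanical properties. Provides global-threshold
    segmentation with 2D despeckling, maximal-inscribed-sphere local thickness
    of the canal network, region-of-interest porosity and volume-weighted canal
    diameter histograms, an ROI scheme that profiles porosity, canal diameter
    and cortical thickness along depth and bone length, continuous two-segment
    (bilinear) modulus extraction from compressive stress-strain records, and
    Pearson correlation reporting. Includes a synthetic voxel phantom generator
    with exact canal-level ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
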