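Package: graintomo
Title: Morphometric Analysis of Wheat Grain Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated analysis of X-ray micro computed tomography scans of
    developing wheat grains. Segments the grain from TIFF slice stacks by pooled
    histogram thresholding, largest connected component selection and median
    filtering; partitions the grain into outer and inner tissue compartments by
    3D morphological opening with a spherical structuring element and detects
    enclosed voids; aligns each grain into a canonical pose from equivalent
    ellipse second moments; extracts dimensions and compartment volumes in
    physical units; and quantifies the depth of the ventral crease along the
    grain with a chord-to-point distance accumulation (CPDA) corner detector.
    Includes a synthetic grain phantom generator with exact ground truth so
    every stage can be validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
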