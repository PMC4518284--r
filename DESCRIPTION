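Package: vasculometry
Title: 3D Microvascular Morphometry for Volumetric Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies three-dimensional vascular architecture in
    high-resolution volumetric angiograms such as synchrotron micro-CT
    scans of the rodent spinal cord. Provides iterative gray-level
    (isodata) thresholding with a 3D size filter, exact Euclidean distance
    mapping, topology-preserving 3D thinning, centerline-to-graph
    conversion, and the standard morphometric read-outs (vessel volume,
    vessel number, vessel node number, diameter distribution, signed
    bifurcation angle), together with a synthetic vascular phantom
    generator with exact ground truth and an injury model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
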