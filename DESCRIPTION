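Package: contactr
Title: Quantification of Lipid Droplet-Mitochondria Contact Sites in
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and measures linear membrane contact sites between
    lipid droplets and mitochondria in multi-channel confocal fluorescence
    images. Cells are individualized from nucleus and cytoplasmic staining
    by prominence-based maxima segmentation, lipid droplets by a trainable
    random-forest pixel classifier, mitochondria by automatic intensity
    thresholding, and contact sites by intensity-ratio colocalization
    followed by skeletonization, yielding per-cell morphometry and
    calibrated contact lengths. Includes a synthetic scene generator with
    ground truth for validation and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    ranger,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
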