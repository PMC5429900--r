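Package: plaquemorph
Title: Automated Segmentation and Morphometry of OMSB-Stained Artery Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic segmentation and morphometric quantification of
    atherosclerotic plaques in polychrome (orcein plus martius scarlet blue,
    OMSB) stained artery cross-sections. Pixels are classified into stain
    classes by HSV color thresholding, elastic laminae are recognised as thin
    closed rings in the purple (orcein) mask, and the vessel is partitioned
    into media, lumen, plaque, lipid and intraplaque collagen compartments by
    mask algebra. Pixel counts are converted to calibrated areas and the
    standard relative parameters (lumen, plaque, collagen and lipid ratios),
    and groups of sections are compared with an exact-capable Mann-Whitney U
    test and Tukey box-and-whisker summaries. A synthetic section generator
    with exact per-compartment ground truth supports end-to-end validation
    without slide material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'plaquemorph-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'imageIO.R'
    'colorModel.R'
    'syntheticData.R'
    'masks.R'
    'laminae.R'
    'segmentation.R'
    'morphometry.R'
    'groupStats.R'
    'cli.R'
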