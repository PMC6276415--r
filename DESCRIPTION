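Package: cephvote
Title: Automatic Cephalometric Analysis by Multiresolution Decision-Tree
    Regression Voting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic analysis of lateral cephalometric radiographs.
    Anatomical landmarks are localized by multiresolution decision-tree
    regression voting (MDTRV): SIFT-style gradient-orientation patch
    descriptors are mapped to landmark displacements by CART regression
    trees, predicted displacements are accumulated by unit voting, and a
    coarse-to-fine scale schedule with an ensemble-voting refinement stage
    produces the final positions.  Detected landmarks feed angular and
    linear cephalometric measurements (five geometry classes over standard
    19- and 45-landmark catalogs), anatomical-type classification, and the
    standard evaluation statistics (mean radial error, success detection
    rate, success classification rate, mean absolute error).  A synthetic
    cephalogram generator with exact landmark ground truth supports
    end-to-end training, detection and evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
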