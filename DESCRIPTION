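Package: zigzagRBC
Title: Label-Free Classification of Red Blood Cells in Zigzag Microchannel Videos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end image analysis of single red blood cells traversing a
    microchannel of periodically oscillating width. Implements event-triggered
    ("soft trigger") single-cell frame extraction with Gaussian-mixture
    background/foreground segmentation, temporal background splicing and
    subtraction, and a compact convolutional neural network that discriminates
    native from chemically stiffened cells from pixels alone. Includes a
    seeded synthetic video generator that renders deformable cell blobs
    flowing through the zigzag channel with full ground truth, so every
    pipeline stage can be validated without laboratory data, plus a small
    calculator for effective shear rate and stress in the channel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
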