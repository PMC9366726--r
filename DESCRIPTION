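Package: MAseg
Title: Microaneurysm Segmentation and Morphometry from Adaptive-Optics
    Retinal Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments retinal microaneurysms (MAs) and their feeding and
    draining vessels from multi-frame adaptive optics scanning laser
    ophthalmoscopy (AOSLO) videos, and quantifies their shape. The
    pipeline builds a temporal-variance perfusion map and an enhanced
    intensity image from each video, concatenates them into a two-channel
    input, trains an encoder-decoder (U-shaped) convolutional network
    under a composite binary cross-entropy plus Dice loss, binarizes and
    clears the predicted probability maps, takes the union over an
    ensemble of cross-validated models, and derives medial-axis
    morphometry: largest caliber (LC), narrowest caliber (NC) and the
    body-to-neck ratio (BNR). A seeded phantom generator emulates the
    statistical structure of AOSLO MA videos (flickering perfused
    structures on noisy static background with distractor vessels) so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
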