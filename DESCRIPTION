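Package: boostseg
Title: Boosted Multilabel Segmentation of Somata and Vessels with Annotation Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A boosting framework for multilabel semantic segmentation of
    neuronal somata and blood vessels in 8-bit grayscale micro-optical
    sectioning tomography (MOST) style images. Provides a two-head
    encoder-decoder network trained with a customized Dice-logarithmic loss
    whose cross-class terms suppress leakage between the soma and vessel
    output heads; a fusion module that recovers strictly-missing annotation
    labels from network predictions via union-find connected-component
    labeling; an AdaBoost-style per-instance, per-class sample-reweighting
    loop; and a seeded synthetic phantom generator with a component-wise
    annotation-corruption model so the whole pipeline is testable end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
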