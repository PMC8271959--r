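Package: oarseg
Title: Attention U-Net Segmentation of Thoracic Organs at Risk in CT with STAPLE Fold Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise segmentation of thoracic organs at risk (esophagus,
    heart, trachea, aorta) in CT volumes. Provides a U-Net variant with a
    ResNet34 or SEResNeXt50 encoder, a group-normalized dual-branch decoder
    with spatial attention modules, and an atrous spatial pyramid pooling
    bottleneck, trained with a combined soft-Dice and weighted cross-entropy
    objective. Includes Hounsfield-unit windowing and NIfTI I/O, Dice and
    (95th-percentile) Hausdorff surface metrics in millimetres, STAPLE
    expectation-maximization fusion of k-fold predictions with a
    majority-voting baseline, and a deterministic phantom generator so the
    whole pipeline runs end-to-end on synthetic data on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
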