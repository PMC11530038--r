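Package: attdunet
Title: Densely Connected Attention U-Net for Ultrasound Lesion Segmentation
Version: 0.1.0
Authors@R: person("attdunet", "maintainers", email = "maintainers@attdunet.org", role = c("aut", "cre"))
Description: Training and evaluation of a densely connected encoder-decoder
    segmentation network with attention gates, channel attention and scale
    attention, aimed at breast-ultrasound-style lesion segmentation. Ships a
    compact reverse-mode automatic differentiation engine with BLAS-backed
    convolution kernels, Dice/Jaccard/PPV/sensitivity/F1 evaluation metrics,
    a PNG folder data pipeline with flip/scale augmentation, a speckle
    phantom simulator for self-contained end-to-end tests, and a command
    line interface for dataset generation, training, evaluation and
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
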