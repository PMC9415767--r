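Package: activens
Title: Learnable Activation Functions and Activation-Replacement Ensembles for Small-Image CNNs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A catalogue of fixed and learnable convolutional-network
    activation functions (ReLU variants, exponential units, Swish/Mish,
    the Mexican-hat MeLU/GaLU family and its symmetric, mixed, flexible
    and two-dimensional extensions) with exact forward values, input
    gradients and learnable-parameter gradients, plus the fixed dyadic
    hat-parameter ladders that define the MeLU/GaLU bases. On top of the
    activation layer the package provides stochastic activation
    replacement over an abstract layer graph, a small trainable CNN for
    desk-scale experiments, sum-rule fusion of classifier probability
    outputs, sequential forward floating selection of ensemble members,
    stratified cross-validation, exact Wilcoxon signed-rank comparison
    and average-rank summaries, and a seeded synthetic image-data
    generator for multi-class benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
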