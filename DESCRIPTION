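Package: leafsight
Title: Leaf Disease Recognition with Custom Self-Attention CNNs and
    Human-Learning-Optimization Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for fruit and vegetable leaf disease
    recognition from RGB images. Provides hybrid contrast enhancement
    (dark-channel-prior dehazing followed by bi-histogram equalization),
    autoencoder-based class balancing, programmatic builders for two custom
    convolutional architectures with self-attention feature taps (a
    bottleneck-residual and an inverted-bottleneck-residual design) including
    layer enumeration and learnable-parameter counting, deep-feature
    concatenation fusion, an improved binary Human Learning Optimization
    wrapper for feature selection with a k-nearest-neighbour holdout fitness,
    and shallow neural-network classifiers evaluated with stratified k-fold
    cross-validation. Seeded synthetic fixture generators make the whole
    pipeline testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    pROC,
    png,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
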