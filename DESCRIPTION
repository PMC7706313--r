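Package: lesionviz
Title: Interpreting Convolutional Neural Networks for Image-Based Plant
    Disease Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for opening the black box of
    convolutional neural network (CNN) classifiers of leaf-disease imagery.
    Provides a minimal layer-graph network engine (including an
    InceptionV3-like builder, exact parameter accounting, truncation surgery
    and a small Adam training loop), a synthetic leaf-lesion image generator
    with ground-truth masks, and four families of visualization methods:
    hidden-layer activation grids, activation-maximization feature
    visualization in a color-decorrelated Fourier parameterization, a
    semantic dictionary of per-neuron contribution scores at the global
    average pooling layer, and eight attention-map algorithms (occlusion,
    superpixel surrogate regression, vanilla and guided back-propagation,
    integrated gradients, Grad-CAM with layer targeting, DeepLIFT rescale,
    and a forward-only explanation map). Attention maps can be scored
    against lesion masks, and visualization-guided layer shaving with
    transfer learning quantifies how many feature-extraction layers a
    diagnosis task actually needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
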