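Package: cellInpaint
Title: Self-Supervised Single-Cell Representation Learning by Paired Cell Inpainting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns feature representations of single cells in multichannel
    fluorescence microscopy images without manual labels, by training a
    convolutional encoder-decoder on a paired cell inpainting pretext task:
    given all channels of one cell and only the structural-marker channels of a
    second cell from the same image, the network predicts the protein channel
    of the second cell. Includes a synthetic multichannel microscopy simulator
    with ground truth, yeast-style (center-based) and human-style
    (Otsu-nucleus) single-cell cropping and normalization, the convolutional
    architecture with named layer taps, spatial max-pooling feature
    extraction, and the evaluation machinery: leave-one-out kNN balanced
    accuracy with a layer sweep, normalized same-term pairwise distances,
    multi-localization log-ratio scores with a single-cell variability screen,
    and agglomerative clustering of protein-averaged features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core-data.R'
    'nn-layers.R'
    'model.R'
    'features.R'
    'evaluate.R'
    'preprocess.R'
    'synthetic.R'
    'train.R'
    'pipeline.R'
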