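Package: histofuse
Title: Fused Deep and Handcrafted Texture Features with
    Hummingbird-Algorithm Selection for Histology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for binary classification of histology-style images
    (healthy versus oral squamous cell carcinoma) by fusing handcrafted
    texture descriptors with deep-feature vectors. Implements weighted
    uniform local binary pattern histograms and one-level Haar wavelet
    subband descriptors, a pluggable deep-feature extractor contract with
    a deterministic mock extractor, the Artificial Hummingbird Algorithm
    as a bounded continuous maximizer with a centroid-distance
    feature-selection wrapper, serial and tanh-weighted ensemble feature
    fusion, a multi-classifier cross-validation bench, and an exact
    confusion-matrix metrics engine. A seeded synthetic two-class texture
    generator makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    glmnet,
    jsonlite,
    png,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
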