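Package: tuberscope
Title: Image-Based Species and Origin Classification of Medicinal Tubers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for identifying the botanical species and
    geographic origin of dried medicinal tubers (Alismatis Rhizoma) from
    single-object photographs. Provides a synthetic tuber-image generator
    with controllable class structure, saturation-based segmentation and
    background whitening, extraction of a 17-element feature vector (three
    shape descriptors, two HSV color means, and twelve gray-level
    co-occurrence matrix texture statistics), feature-fusion ablation over
    four classifiers including a from-scratch extreme learning machine, and
    a full evaluation stack (confusion matrices, macro metrics, stratified
    10-fold cross-validation, one-way ANOVA with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    MASS,
    randomForest,
    e1071,
    nnet,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
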