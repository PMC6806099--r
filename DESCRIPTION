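Package: uosdfs
Title: Unsupervised Online Feature Selection for Multispectral Quality Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic feature selection (DFS) for classifying multispectral-imaging
    samples into microbiological quality classes. Implements Fisher-discriminant-score
    feature elimination on the training set, two per-test-sample online rejection
    criteria (a per-feature Mahalanobis distance ratio and a maximum Gaussian class
    probability), exhaustive threshold optimization on a validation split, and a
    pluggable linear classifier layer (linear-kernel SVM, LDA, QDA). Includes a
    synthetic multispectral data generator with batch effects, drift and outlier
    contamination, feature extraction from image cubes via Gaussian-mixture
    segmentation, and an evaluation suite (confusion metrics, microbial-load bin
    tables, feature selection-rate reports, static-selection baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    MASS,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
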