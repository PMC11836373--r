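Package: octaco
Title: Ant-Colony-Optimized Transformer Classification of Retinal OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of retinal optical coherence tomography (OCT) B-scans
    into CNV, DME, Drusen and Normal with a hybrid pipeline: wavelet-domain
    preprocessing with significance-based coefficient retention, ant colony
    optimization (ACO) over discrete search spaces (augmentation-policy search,
    hyperparameter tuning, wrapper feature selection), SMOTE oversampling with
    weighted cross-entropy for class imbalance, and a modified Vision
    Transformer with multi-scale patch embeddings, windowed self-attention,
    relative positional bias and content-aware attention weighting. Includes a
    synthetic generator of layered OCT-like B-scans with speckle noise and
    class-specific lesions so the whole pipeline is testable without the
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
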