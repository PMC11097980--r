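Package: gclink
Title: Graph-Contrastive Link Prediction for Drug-Gene Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unknown drug-gene associations from a sparse bipartite
    association graph by self-supervised graph-contrastive learning. A
    light-weight graph convolutional encoder propagates learnable node
    embeddings over the degree-normalized bipartite adjacency, a second
    "global" view is built from a truncated randomized singular value
    decomposition of the same adjacency, and an InfoNCE contrastive loss
    aligns the two views while a pairwise hinge ranking loss fits observed
    edges. Includes a planted-block synthetic graph generator, a k-fold
    link-prediction cross-validation harness with AUC/AUPR/recall/precision/F1
    reporting, top-k candidate ranking, and ablation/sensitivity experiment
    suites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
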