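Package: dnmfdr
Title: Deep Non-Negative Matrix Factorization for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations by deep (multi-layer)
    non-negative matrix factorization of integrated similarity/association
    matrices, with graph-Laplacian regularization on every layer's basis,
    relaxation terms tying adjacent layers together, and multiplicative
    update rules derived from KKT conditions. Includes weighted k-nearest
    neighbour preprocessing of empty association profiles (cold-start
    drugs and diseases), similarity fusion by averaging, layer-wise NMF
    pretraining, ranked candidate output, and two evaluation protocols:
    10-fold cross-validation over known associations and a cold-start
    test over drugs with a single known indication. A synthetic-data
    generator with a planted low-rank association signal makes the whole
    pipeline testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
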