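Package: pseudoshaper
Title: Ensemble Linear Trajectory Inference for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers a linear pseudotime for single-cell RNA-seq data with an
    ensemble of discrete pseudotimes. Each discrete pseudotime is a k-means
    clustering whose labels are permuted along the (greedily solved) shortest
    Hamiltonian path through the cluster centroids; sweeping k over a range
    yields a set of discrete pseudotimes that are aggregated via the loadings
    of the first two principal components and smoothed with local polynomial
    regression (LOESS) into a continuous pseudotime in [0, 1]. Includes a
    trigonometric trajectory simulator with ground truth, evaluation metrics
    (RMSE, Pearson and Spearman correlation after direction alignment),
    PCA/t-SNE preprocessing helpers, readers for dense CSV/TSV and Matrix
    Market expression matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite
Suggests:
    Rtsne,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
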