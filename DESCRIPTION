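Package: reDA
Title: Cluster-Free Differential Abundance Testing for Multi-Sample scATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cell states whose abundance covaries with a sample-level
    phenotype in multi-sample single-cell ATAC-seq data, without clustering.
    Cells are embedded by TF-IDF/LSI, connected in a shared-nearest-neighbor
    graph, and soft neighborhoods are defined by a random walk with restart
    whose step count is chosen by a kurtosis-based balance rule. The resulting
    sample-by-cell neighborhood abundance matrix is tested against the
    phenotype with a selection-aware permutation framework (PCA of the
    abundance matrix, a global association test, per-cell neighborhood
    coefficients, and an empirical false discovery rate). Includes a synthetic
    multi-sample scATAC-seq generator with planted differentially abundant
    subpopulations and a paired benchmark harness for restart-probability and
    walk-length ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    irlba,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
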