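Package: netboot
Title: Bootstrap Subsampling for Goodness of Fit and Model Selection with a Single Observed Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Node-wise bootstrap subsampling for statistical procedures on a
    single observed network. Resampling distributions of user-chosen network
    statistics are built from induced subgraphs of uniform node subsamples and
    compared against the analogous distributions from candidate generative
    models, supporting goodness-of-fit assessment, classifier-based model
    selection with majority-rule confidence, and pairwise comparison of
    multiple observed networks. Includes mechanistic network simulators
    (Erdos-Renyi growth, duplication-mutation-complementation,
    duplication-mutation-random, and a triangle-closure variant of G(n,m)),
    seed-network constructors used in duplication-divergence fits of
    protein-protein interaction data, and reproduction harnesses for the
    accompanying simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
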