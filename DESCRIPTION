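Package: kiedra
Title: Kernel-Guided Probabilistic Model-Building Evolution for Feature
    Relevancy and Dependency Discovery
Version: 0.1.0
Authors@R:
    person("Nicolas", "Verano", email = "nverano@posteo.net", role = c("aut", "cre"))
Description: Wrapper feature selection that evolves a bivariate, forest-factored
    probability model (BMDA) over binary relevance indicators, guided by the
    cross-validated accuracy of a weighted-kernel support-vector classifier.
    Pairwise dependencies between features are scored with chi-square, mutual
    information or a combined (SIM) criterion and assembled into a maximum
    dependency spanning forest with minimum-entropy roots; the univariate
    (UMDA) degeneration, wKiera, is included. Ships a model-free epistasis
    simulator (pure k-way parity interactions among SNP-like genotypes plus
    uniform noise features), the multi-repetition aggregation protocols
    (relevance averaging, thresholding, dependency-count aggregation, Kruskal
    consensus trees) and discovery scoring for case-control benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
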