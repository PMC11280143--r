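Package: fosmap
Title: Whole-Brain Axon and c-Fos Mapping with Correlation Network Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Atlas-compartmentalized quantification of axonal-label and c-Fos
    signals from serial coronal sections, structure-wise nonparametric
    comparisons along the anterior-posterior axis (Friedman tests with
    Bonferroni post hocs and summed-difference effect metrics), a
    rewiring-versus-activity correlation classifier with reshuffled permutation
    nulls, significance-gated interregional c-Fos correlation networks with
    degree/participation centrality and Louvain community detection tuned
    against edge-shuffled null networks, exact paired Wilcoxon behavior
    statistics, and injection-site KNN separability checks. Ships a synthetic
    data generator (toy atlas, cohorts with planted effects and latent
    correlation communities, rendered section images, paired behavior tables)
    so every stage is testable without imaging data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
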