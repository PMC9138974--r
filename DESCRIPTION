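Package: phispike
Title: Integrated Information (Phi) for Spike-Train Data with Partition Approximations
Version: 0.1.0
Authors@R:
    person("phispike", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Computes the autoregressive integrated information coefficient
    (Phi-AR) on binarized spike-train recordings under three partition
    approximations: exhaustive minimum-information bipartition search, the
    atomic (all-singletons) partition, and a community partition found by a
    from-scratch Louvain modularity optimizer over a significance-thresholded
    spike-correlation network. Includes Bernoulli-variance neuron selection
    with an iterative-removal loop for rank-deficient covariance matrices,
    lag (delta-t) optimization by Phi maximization, a session-period analysis
    pipeline correlating Phi with behavioral reward rates (Spearman,
    Bonferroni-corrected), and seeded synthetic spike-train generators with
    planted coupling, community, and reward structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
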