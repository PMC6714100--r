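Package: rankrobust
Title: Rank Robustness of Node Metrics in Score-Thresholded Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing how robust node-metric rankings are to the
    choice of confidence-score threshold in scored (protein) interaction
    networks. Provides readers and writers for scored edge lists, threshold
    sweeps that preserve the node set, twelve node centralities and thirteen
    leave-one-out-difference (LOUD) global network summaries, full node
    rankings with random tie-breaking, top-k rank overlap statistics
    (k-similarity and its relaxed asymmetric variant), and three robustness
    measures: rank continuity, rank identifiability, and rank instability.
    Includes generators for synthetic scored networks (Bernoulli random
    graphs with empirically resampled scores, score-shuffled induced
    subgraphs, and a heterogeneous scale-free fixture) so the whole pipeline
    can be exercised without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
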