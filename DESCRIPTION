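Package: mrmrpath
Title: Surrogate Gene Discovery by mRMR Feature Selection and
    Interaction-Network Shortest Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies minimal surrogate gene sets that classify samples
    into disease phases from expression profiles. Features are ranked by the
    minimum-redundancy maximum-relevance (mRMR) criterion using a
    Gaussian correlation-based mutual-information estimator, nested feature
    subsets are scored by jackknife (leave-one-out) validation under three
    nearest-neighbor-style prediction engines with a cosine sample distance,
    and the smallest subset attaining maximal accuracy is selected by
    incremental feature selection. Selected genes are then placed on a scored
    protein-protein interaction network and joined by shortest paths to
    recover bridging genes. Includes a synthetic-data generator with known
    ground truth (planted phase-informative probes, redundant probe copies,
    and planted bridge paths) so the whole pipeline is testable without
    external data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
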