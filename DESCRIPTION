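Package: acunet
Title: Key-Node Mining in Weighted Acupoint-Disease Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted undirected co-occurrence networks from
    condition-to-entity prescription tables (each prescription induces a
    clique whose edge weights count shared conditions), scores nodes with a
    matrix-power influence index summed over walk lengths up to the network
    diameter, and selects key nodes under a fixed community partition via a
    two-stage closeness-then-influence pipeline. Ships six baseline
    centralities and three evaluation indexes: ranking resolution,
    node-deletion connectivity loss, and a weight-reduction benchmark
    compared through Kendall's tau.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
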