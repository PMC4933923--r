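Package: egonetdis
Title: Alignment-Free Network Comparison with Netdis and Ego-Network Sub-Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Netdis alignment-free network-comparison statistic
    from counts of small connected subgraphs (3- and 4-node graphlets) in
    two-step ego-networks, centered against a density-matched reference
    network, together with uniform ego-network sub-sampling and a
    seed-plus-neighbourhood bootstrap that make the statistic applicable to
    very large or partially observed networks. Includes generators for six
    random-graph benchmark models, nearest-neighbour cluster-recovery scores,
    and neighbourhood-balance diagnostics that flag networks where
    sub-sampling is likely to fail.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
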