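Package: tempoalign
Title: Alignment of Co-Evolving Temporal Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies co-evolving subnetworks in a pair of temporal
    biological networks by computing a single node mapping that remains
    high-scoring across all time points. Node-pair similarities are obtained
    by IsoRank-style propagation of homology scores through the topology of
    each snapshot, aggregated over time, and turned into an initial alignment
    by maximum-weight bipartite matching. The alignment is then refined by a
    dynamic program that swaps aligned target nodes with gap nodes to reduce
    the number of connected components of the aligned region, under an
    edge-insertion penalty that guarantees monotone score improvement. Ships
    with a co-evolving network simulator (scale-free target, planted
    connected query, cold/hot edge turnover, log-normal homology) and
    evaluation metrics (recovered region, induced conserved structure, edge
    correctness, z-score against random alignments).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
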