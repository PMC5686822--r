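Package: rwrmtn
Title: Disease miRNA Prioritization by Random Walks on Mutual
    miRNA-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease-associated microRNAs by network
    propagation. Builds heterogeneous (bipartite miRNA-target) and
    homogeneous (shared-target similarity) miRNA networks from interaction
    edge lists, runs a random walk with restart seeded by known disease
    miRNAs and, on heterogeneous networks, also by their target genes
    (RWRMTN), and ranks all remaining miRNAs by steady-state visiting
    probability. Includes the RWRMDA random-walk comparator on homogeneous
    networks and the RLSMDA regularized least-squares comparator, a
    leave-one-out and k-fold cross-validation harness with ROC/AUC
    summaries, parameter-sweep utilities, top-k hypergeometric enrichment
    against a reference association database, and seeded generators of
    synthetic interaction data with planted disease modules for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
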