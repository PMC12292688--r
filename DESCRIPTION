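Package: netpharm
Title: Network Pharmacology Pipeline for Hub-Gene Identification and
    Pathway Enrichment
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable, fully offline network-pharmacology workflow:
    aggregation of disease and compound target genes from multi-source
    tables, construction of a confidence-filtered protein-protein
    interaction (PPI) network from STRING-format edge lists, six node
    centrality measures (degree, betweenness, closeness, eigenvector,
    local average connectivity, maximal clique centrality), iterated
    median-threshold extraction of a critical subnetwork, Degree/MCC
    hub-gene ranking, and hypergeometric over-representation analysis of
    GMT pathway collections with fold enrichment and Benjamini-Hochberg
    FDR. A synthetic-data module generates scored gene lists, scale-free
    PPI networks with planted hubs, and pathway collections with planted
    enrichment, so every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
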