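Package: netpharm
Title: Network Pharmacology of Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and topological analysis of typed multipartite
    networks for multi-compound herbal formulas: herb-compound-target and
    protein-protein interaction network builders with role labelling,
    degree/betweenness/closeness centrality with above-mean main-node (hub)
    selection, fold-enrichment and hypergeometric over-representation
    analysis with functional-module partitioning, and seeded synthetic-data
    generators that emulate pharmacophore-mapping target tables, scored
    interaction exports and gene-set annotations so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
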