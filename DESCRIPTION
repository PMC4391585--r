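Package: ncxnet
Title: Differential ncRNA-mRNA Coexpression Network Analysis
Version: 1.0.0
Authors@R: person("ncxnet", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds condition-specific bipartite ncRNA-mRNA coexpression
    networks from expression matrices by thresholding pairwise Pearson
    correlations at a significance-derived cutoff, characterizes their
    topology (degree distributions, power-law fits, betweenness-outdegree
    combined centrality, hub extraction, network descriptors), compares
    networks edge-by-edge to extract a status-independent core and a
    disease-specific network, performs Rank Products differential
    expression, and selects candidate therapeutic ncRNAs by combining
    network centrality with differential expression. A synthetic-cohort
    generator with planted regulatory structure makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
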