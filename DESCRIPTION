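Package: hubpanel
Title: Hub-Bottleneck Gene Nomination from Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for nominating candidate biomarker genes
    shared across related diseases from protein-protein interaction (PPI)
    networks. Starting from per-disease gene lists, the package computes
    their common core, assembles an undirected interaction network (generic
    edge lists or STRING protein.links tables), decomposes it into connected
    components, ranks nodes of the main component by degree, betweenness,
    closeness and stress centrality, calls hubs (degree above mean plus two
    standard deviations) and bottlenecks (top betweenness fraction), detects
    dense molecular complexes with an MCODE-style seeded clustering
    algorithm, and tests annotation terms for over-representation with a
    hypergeometric test, Benjamini-Hochberg correction and kappa-statistic
    term grouping. A synthetic-data module generates all pipeline inputs
    with planted ground truth (gene-list cores, scale-free networks with
    planted hubs, dense complexes, enriched term blocks) so every stage can
    be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
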