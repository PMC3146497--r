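Package: graphproto
Title: Graph Prototype Selection for Cohorts of Uniquely-Labeled Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a prototype network from a cohort of undirected,
    uniquely-labeled graphs as the member with minimal mean distance to all
    other members. Implements five structural distance measures: the
    normalized graph edit distance for graphs on a fixed labeled vertex set,
    and Kullback-Leibler divergences between degree, shortest-path distance,
    sphere-based vertex probability, and automorphism-orbit distributions.
    Includes between-group Wilcoxon comparison of within-group distances with
    Bonferroni correction, min-max normalized feature clustering, topological
    characterization of selected prototypes (hub degrees, eccentricities,
    diameter, average path length, clustering coefficient), and a synthetic
    cohort generator producing sparse scale-free graphs on a shared label set
    with controlled rewiring noise and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
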