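Package: netpharm
Title: Network Pharmacology Inference for Herbal Ingredient-Target-Disease Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, offline re-usable implementation of the network
    pharmacology inference chain used to study multi-compound herbal
    medicines: ADME screening of ingredients by oral bioavailability and
    drug-likeness, assembly and intersection of ingredient targets with
    disease gene sets, construction and topological analysis of
    ingredient-target bipartite networks and confidence-filtered
    protein-protein interaction networks, hypergeometric
    over-representation analysis with Benjamini-Hochberg false discovery
    rate control, and integration of enriched pathways into a curated
    disease pathway model. Includes seeded synthetic-data generators that
    emulate the statistical shape of herb screening tables, target maps,
    disease gene lists, scored interactomes and gene-set annotations, so
    every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
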