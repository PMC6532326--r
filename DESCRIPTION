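Package: herbnet
Title: Network-Pharmacology Inference for Herb-Ingredient-Target-Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for network-pharmacology inference over
    multi-herb formulas: ADME screening of herbal ingredients by oral
    bioavailability and drug-likeness, assembly of a deduplicated
    ingredient-target compendium from validated and predicted associations,
    disease-gene derivation by two-group differential expression plus curated
    database lists, candidate-target intersection, confidence-filtered
    protein-protein interaction expansion, tripartite network construction
    with degree-based hub selection, and hypergeometric gene-set enrichment
    with kappa-statistic term grouping. Includes a synthetic-data generator
    with planted ground truth so every stage is verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
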