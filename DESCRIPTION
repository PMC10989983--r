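Package: metaborigin
Title: Origin-Aware Integration of Microbiome and Metabolome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies metabolites by biological origin (host, microbiota,
    co-metabolism, food, drug, environment) against an offline knowledge base
    of metabolite source records, performs origin-scoped metabolic pathway
    enrichment with hypergeometric tests, correlates microbial taxa with
    metabolites at every taxonomic rank, and builds reaction-centric Sankey
    networks and per-origin summary networks that integrate biological and
    statistical evidence. Ships seeded generators for miniature knowledge
    bases and two-group microbiome-metabolome studies with planted structure,
    so the whole pipeline runs end to end without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
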