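Package: degnet
Title: Topology-Informed Pre-Processing of Differential Expression Gene
    Lists for Pathway Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a raw differential-expression gene list into compact
    up- and down-regulated "relevant gene" sets using rank-based
    co-expression similarity networks (Kruskal-Wallis p values as a
    similarity measure), closeness-centrality filtering, protein-protein
    interaction neighborhood expansion and bottleneck-centrality selection,
    then performs hypergeometric pathway over-representation analysis with
    false discovery rate and Bonferroni control. Includes readers for
    GEO2R-style differential-expression tables, expression matrices,
    tab-delimited protein-interaction edge lists and GMT pathway
    collections, and a deterministic synthetic study generator with
    planted co-regulated modules for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
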