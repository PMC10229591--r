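Package: florealm
Title: Phylogenetic Delineation of Floristic Realms and Their Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative floristic regionalization from a dated genus-level
    phylogeny and a genus-by-region occurrence matrix. Computes taxonomic and
    phylogenetic Simpson (turnover-only) beta diversity, delineates nested
    floristic realms by UPGMA clustering with explained-turnover (P-beta)
    dendrogram cuts, reconstructs the divergence chronology of realms by
    slicing the phylogeny at successive depths, attributes realm boundaries to
    geographic isolation versus climate through geological time with
    least-cost route costs and hierarchical partitioning, and scores the
    contribution of individual clades to realm divisions via geographic node
    divergence (GND) and site-level overrepresentation (SOS) statistics. A
    synthetic-world generator with planted realms, divergence times, climates
    and paleo-landscapes makes every stage verifiable against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    cluster,
    igraph,
    geosphere,
    jsonlite,
    mclust,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
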