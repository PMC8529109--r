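Package: funloss
Title: Directed Species-Loss Simulation and Taxonomy-Function Decoupling
    for Metagenomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates directed, abundance-ordered phylum removal on paired
    taxonomy and function profiles from shotgun metagenomes and quantifies
    whether functional beta-diversity is more stable than taxonomic
    beta-diversity. Provides a joint taxonomy-by-function profile container,
    a synthetic soil-community generator with tunable cross-taxon functional
    redundancy, from-scratch Bray-Curtis, principal coordinates analysis and
    permutational multivariate ANOVA (main and pairwise tests),
    function-category response statistics with Spearman/UPGMA heatmap
    clustering, correlation-based co-occurrence networks with a random-matrix
    similarity threshold scan, and a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
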