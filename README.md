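# funloss

Directed species-loss simulation and taxonomy–function decoupling analysis
for shotgun-metagenome profiles.

## The problem

Biotic homogenization — the worldwide replacement of diverse communities by a
few dominant taxa — raises a central question for soil microbial ecology: when
most taxa disappear, does community *function* disappear with them? Because
many taxa encode the same genes (functional redundancy), the functional
profile of a community can in principle stay stable while its taxonomic
profile collapses.

`funloss` studies this in silico. Starting from a joint per-sample
taxonomy-by-function annotation table (genus with its phylum × function with
its Subsystems-style level 1–3 lineage × hit count, the shape of MG-RAST
RefSeq/Subsystems exports), it simulates **directed, abundance-ordered
species loss**: phyla are ranked by pooled relative abundance and removed
from the bottom of the ranking, producing a nested series of retention sets
(e.g. All → 8 → 5 → 2 → 1 phyla). Because every record carries the joint
(genus, function) key, removing a phylum removes the functional hits its
genera carried — the taxonomy filter and the functional profile stay coupled
exactly as in a database-side taxonomy filter.

The package then quantifies, per loss level and between levels:

- **Beta-diversity.** Bray–Curtis dissimilarity
  `D_ij = Σ_k |x_ik − x_jk| / Σ_k (x_ik + x_jk)` on relative abundances
  (similarity = 100·(1−D)%), principal coordinates analysis (PCoA), and
  one-factor PERMANOVA: `pseudo-F = (SS_between/(a−1)) / (SS_within/(N−a))`
  with `SS_total = (1/N)·Σ_{i<j} d²_ij`, permutation p-values
  `(1+b)/(1+m)`, and pairwise `pseudo-t = √pseudo-F`. All of this is
  implemented from scratch and cross-checked against independent oracles.
- **Function-specific responses.** Mean relative abundance of level-1
  categories per loss level, one-way ANOVA F per category, PERMANOVA on
  within-category renormalized function profiles, the Pearson correlation of
  a category's statistic with its abundance, and Spearman-distance / UPGMA
  heatmap clustering of the category × level matrix.
- **Co-occurrence networks.** MENA-style pipeline: prevalence filter
  (> 1/2 of samples), 0.01 fill for blanks, log10 transform, Pearson
  similarity, an |r| threshold S_t (fixed, or selected by a random-matrix
  eigenvalue-spacing scan), greedy-modularity modules, and the standard
  index panel (nodes, links, connectivity, clustering coefficient, geodesic
  distance, modularity, % negative links), exported as Cytoscape-compatible
  edge/node tables.

A synthetic-community generator with tunable cross-taxon functional
redundancy (ρ) stands in for a real metagenome corpus, so the whole pipeline
is testable end to end without downloads: at ρ → 1 every genus shares one
core gene profile and function is provably stable under any extinction; at
ρ = 0 function tracks taxonomy.

## Worked example

```r
library(funloss)

cfg <- syntheticConfig(nSamples = 20, nPhyla = 8, generaPerPhylum = 6,
                       nFunctions = 48, redundancy = 0.9, seed = 2024)
profile <- generateCommunity(cfg)
profile
#> LinkedProfile: 20 samples, 48 genera in 8 phyla, 48 functions
#>   records: 34230  total hits: 1,999,391

levels <- defaultLevels(rankPhyla(profile), c(8, 5, 2, 1))
report <- lossSeries(profile, levels)
report
#> Loss-series report over 4 levels
#>  level     kind index retained_phyla  S       N pct_reduction_S pct_reduction_N
#>    All function     1              8 48 1999391             0.0        0.000000
#>    All taxonomy     1              8 48 1999391             0.0        0.000000
#>   Five function     2              5 48 1945679             0.0        2.686418
#>   Five taxonomy     2              5 30 1945679            37.5        2.686418
#>    Two function     3              2 48 1513862             0.0       24.283844
#>    Two taxonomy     3              2 12 1513862            75.0       24.283844
#>    One function     4              1 48 1063900             0.0       46.788797
#>    One taxonomy     4              1  6 1063900            87.5       46.788797
```

Dropping from 8 phyla to 1 removes 87.5% of genera (and ~47% of all hits),
yet at ρ = 0.9 every function category survives. The beta-diversity
comparison makes the decoupling quantitative — loss level explains far more
taxonomic than functional variation:

```r
st <- stackLevels(report, "taxonomyRelative")
permanova(brayCurtis(st$x, relative = FALSE), st$groups,
          nPermutations = 999, seed = 1)
#> PERMANOVA: pseudo-F = 28.33 on df (3, 76), R2 = 0.5279, p = 0.001 (999 permutations)

sf <- stackLevels(report, "funcRelative")
permanova(brayCurtis(sf$x, relative = FALSE), sf$groups,
          nPermutations = 999, seed = 1)
#> PERMANOVA: pseudo-F = 6.622 on df (3, 76), R2 = 0.2072, p = 0.001 (999 permutations)
#> mean Bray-Curtis similarity: taxonomy 64.2%, function 98.2%
```

`runPipeline(runConfig(cfg, ...))` runs all stages at once and writes a
deterministic report bundle (`loss_report.tsv`, `permanova_*.tsv`,
`pcoa_*.tsv`, `category_response.tsv`, `heatmap_matrix.tsv`,
`network_indexes.tsv`, per-level Cytoscape exports, `manifest.json`); two
runs with the same config and seed are byte-identical.

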