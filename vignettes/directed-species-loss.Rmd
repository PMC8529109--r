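---
title: "Directed species loss and the stability of microbial functional structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed species loss and the stability of microbial functional structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funloss)
```

## The question and the design

Soil metagenomes annotated against both a taxonomic reference (phylum →
genus) and a functional hierarchy (Subsystems-style level 1 → level 2 →
level 3 → function) allow a joint view of *who is there* and *what they
encode*. `funloss` asks how that joint structure responds to **directed
species loss**: extinction ordered by a trait, here phylum relative
abundance, with the least abundant phyla removed first. This is the
homogenization scenario — a community collapsing onto its dominant taxa —
rather than random thinning.

The unit object is the `LinkedProfile`: long-format records
`(sample, genus, phylum, function, level1..3, hits)`. The joint key is the
load-bearing design choice. Filtering phyla removes entire records, so the
functional profile of the filtered community is exactly the functional
content of the surviving taxa; taxonomy and function can never get out of
sync (the "joint-key contract", asserted in the tests as: function-table
total N = taxonomy-table total N at every loss level).

A loss series is a nested sequence of retention sets built from the pooled
abundance ranking (ties broken lexicographically so the design is
deterministic). The classic series retains all, 8, 5, 2 and 1 phyla;
`defaultLevels()` reproduces it and accepts any strictly decreasing size
vector. Per level we report corpus-level richness S (features with pooled
hits > 0) and individuals N (total hits), with percent reductions against
the full community; per-sample richness is derivable from the tables but S
is the headline statistic because the loss design is corpus-wide, not
per-sample.

## The synthetic community generator

Real corpora of hundreds of soil metagenomes are not downloadable at desk
scale, so the generator produces communities with the statistical features
the analysis actually relies on:

| parameter | meaning | default |
|---|---|---|
| `nSamples` | metagenomes in the corpus | 40 |
| `nPhyla` | phyla; share of rank r ∝ `phylumDecay^r` | 10 |
| `phylumDecay` | geometric decay of ranked phylum shares (0,1) | 0.5 |
| `generaPerPhylum` | genera nested in each phylum, Dirichlet(1) shares | 8 |
| `nFunctions` | function-level categories | 50 |
| `redundancy` (ρ) | weight of the shared core gene profile in [0,1] | 0.9 |
| `depth` | expected hits per sample | 1e5 |
| `dispersion` | σ of log-normal per-(sample, genus) noise | 0.5 |

Genus g's function profile is `ρ·π_core + (1−ρ)·π_g`, both symmetric
Dirichlet(0.5) draws over functions, with one core draw shared by all
genera. Counts are Poisson with mean `depth × abundance × profile`, after
per-sample log-normal perturbation of genus abundances. Everything is
deterministic given the seed, and the generator restores the caller's RNG
state.

The defaults are the package's study conditions: a 40-sample corpus is
enough for five loss levels with 40 samples each in the concatenated
design; `phylumDecay = 0.5` gives the few-dominant-phyla long tail typical
of soil (top two phyla ≈ 75% of hits); `dispersion = 0.5` produces the
order-of-magnitude abundance scatter seen across field samples; ρ = 0.9
encodes high but not total functional redundancy. The upper functional
hierarchy is deterministic (functions pair into level-3 subsystems, pairs
into level 2, triples into level-1 categories) — enough structure to
exercise every level-aware operation.

What the generator does **not** emulate: real taxon names, biome or study
covariates, the severe sample-size imbalance of literature corpora, and
ecological co-occurrence structure beyond compositional closure. Passing
tests therefore demonstrate the pipeline's correctness and the
redundancy–stability mechanism, not any real-world effect size.

Two limit properties pin the mechanism down and are tested: at ρ = 1 with
no dispersion the pooled function profile is invariant under *any* phylum
removal (Bray–Curtis similarity pre/post > 99%, the residual being Poisson
noise), and at ρ = 0 the same removal measurably shifts it.

## Beta-diversity statistics

All multivariate statistics are implemented in the package and verified
against independent routes (vegan, `cmdscale`-style analytic cases,
brute-force enumeration) in the test suite.

* **Bray–Curtis.** `D_ij = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)` on per-sample
  relative abundances (the standard treatment for uneven sequencing
  depth). A pair of all-zero samples has no defined share and is set to
  D = 0 with a message. No square-root or other pre-transform is applied by
  default.
* **PCoA.** Gower double centering of −½D², symmetric eigendecomposition,
  coordinates scaled by √max(λ, 0). Axis signs are fixed by forcing the
  largest-magnitude loading positive, so results are bit-deterministic.
  Negative eigenvalues (Bray–Curtis is non-Euclidean) are kept in the
  result but excluded from the percent-variation denominator.
* **PERMANOVA.** One-factor partition
  `SS_total = (1/N)·Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g)·Σ_{i<j∈g} d²`,
  `pseudo-F = (SS_between/(a−1))/(SS_within/(N−a))`, p estimated as
  `(1+b)/(1+m)` so p is never 0 and never below `1/(m+1)`. Permuted
  statistics are counted as exceeding at `F_obs − 1e-8·max(1, |F_obs|)`:
  permutations that reproduce the observed partition must tie exactly, and
  the tolerance keeps floating-point summation order from dropping them
  (without it the exact-enumeration comparison on tiny designs would be
  off by one split). Labels are permuted without restriction by default —
  the one-factor treatment of the loss-level design — but a `strata`
  argument restricts shuffling to within blocks for the repeated-measures
  reading in which each metagenome appears once per level.
* **Pairwise tests.** Each unordered pair's sub-matrix gets the two-group
  test; `pseudo-t = √pseudo-F`. Unadjusted p-values by default (the
  PRIMER-style report); any `p.adjust` method can be switched on.
* **Pearson.** r with the two-sided t-approximation p-value; used for the
  S/N decline linearity and the abundance–response panel.

The concatenated design deserves a note: the five loss levels are the same
metagenomes filtered five ways, stacked as `"<sample>@<level>"` rows with
level as the single factor. This mirrors how a taxonomy-filtered corpus is
compared level against level; the `strata` option exists because
exchangeability across levels is an approximation.

## Function-specific responses

Level-1 categories partition the function table, so per-sample category
abundances sum to the classified fraction. The panel reports, per category:
mean relative abundance per level (dominance cutoffs are parameters, 1% for
the trend report and 0.5% for the statistic panel); one-way ANOVA F of the
per-sample abundances against level (`stats::lm`/`anova`; the univariate
Euclidean PERMANOVA limit equals it, which the tests assert to 1e-10);
and a PERMANOVA on the category's *internal* composition — member functions
renormalized to sum 1 per sample — so the statistic is invariant to the
category's overall abundance by construction. Categories with one member
function or too few non-empty samples are skipped with a message.

"Normalized relative abundance" for the heatmap is implemented as a
per-category z-score across levels (row mean 0, sd 1); since z-scoring is a
monotone affine map per row, row ranks — and hence the Spearman distances
and the whole clustering — are invariant to it. Distance between rows is
`1 − Spearman ρ` with average ranks on ties; a constant row has no defined
ranks and is assigned the maximal distance 2 to every other row and
flagged. Agglomeration is UPGMA via `stats::hclust(method = "average")`,
whose merge trace the tests pin against a hand computation.

## Co-occurrence networks

The per-level network pipeline follows the molecular-ecological-network
recipe: keep features present in strictly more than half the samples, fill
remaining zeros with the 0.01 pseudo-abundance, log10, Pearson correlation
across samples, then threshold on |r| at S_t, keeping sign(r) as an edge
attribute (negative links are a reported quantity, so discarding sign is
not an option). Nodes are edge endpoints only; modules come from
Clauset–Newman–Moore greedy modularity (igraph), with the dendrogram cut at
the modularity-maximizing step chosen explicitly — the library's default
cut can return a worse partition on very small graphs. Geodesic distance is
averaged over connected pairs and the component count is reported
alongside. The index panel (nodes, links, `2·links/nodes` connectivity,
mean local clustering with degree-<2 nodes counted 0, geodesic, modularity,
% negative links) is pinned to closed forms on canonical graphs in the
tests.

Two thresholding methods are provided. `fixed` (default S_t = 0.80) is the
reproducibility workhorse. `scan` is a random-matrix-theory heuristic:
ascending candidate cutoffs, and at each the nearest-neighbour spacing
distribution of the adjacency eigenvalues (normalized to unit mean — a
global unfolding; degenerate spectra of sparse modular graphs pile
spacings at zero, exactly the exponential signature) is tested by
chi-squared goodness of fit against the Poisson law versus the Wigner
surmise. The smallest cutoff at which Poisson fits better is returned —
the transition from a correlated to an uncorrelated spectrum. The scan is
deliberately simple; it is a documented alternative, not a reimplementation
of any proprietary pipeline default, and it requires at least 10 features.

On synthetic relative-abundance tables the correlations the networks pick
up are dominated by compositional closure (dominant features co-vary
negatively). That is real structure of the compositional data — and it is
why the function networks, whose profiles are closed over a shared core,
show a higher negative-link fraction than the taxonomy networks — but it is
not ecological interaction, and no ecological claim should be read into the
synthetic networks.

## The pipeline and determinism

`runPipeline()` chains every stage under one config and writes
`loss_report.tsv`, `permanova_*` / `pairwise_*` / `pcoa_*` tables,
`category_response.tsv`, `heatmap_matrix.tsv`, `linkage.tsv`,
`network_indexes.tsv`, per-level Cytoscape exports and a `manifest.json`
(package version, seed, config md5). Every table carries `# stage:` /
`# params:` comment headers; numbers are written with 12 significant
digits. Every stochastic stage derives its seed from the master seed by a
fixed offset, so two runs with one config are byte-identical — asserted
file-by-file in the tests. Taxonomy networks are built at genus and
function networks at level 3 by default (configurable), matching the
resolution at which such panels are usually reported.

## Problem sizes and numerical choices

The test suite exercises the statistics at the sizes where exact oracles
exist (6-sample exhaustive enumeration; 24-sample type-I-error replicates;
50 ANOVA-equivalence draws) and the full pipeline on corpora of 8–40
samples, 4–10 phyla and 20–50 functions; the headline decoupling experiment
uses 20 seeds of the default 40-sample configuration at ρ = 0.9 versus
ρ = 0 with 999-permutation tests. Tolerances: algebraic identities at
1e-10–1e-12; the Monte-Carlo-versus-exact p comparison at 0.005 with 1e5
permutations; law-of-large-numbers checks at 1–2%.

Degenerate inputs are contracts, not crashes: all-zero sample rows survive
normalization with a warning; empty loss levels warn and propagate; a
category or feature that cannot support its statistic is skipped with a
message; an empty network reports a zeroed index panel. Validity methods on
the S4 classes enforce the structural invariants (non-negative hits, unique
keys, nested levels, row sums after normalization) at construction time.

## Known limitations

- The loss design reuses the same samples at every level; the default
  unrestricted permutation ignores that pairing (the `strata` option is the
  conservative alternative).
- The generator's independence assumptions (Poisson cells, independent
  log-normal noise) leave no true ecological co-occurrence signal; network
  results on synthetic data characterize the pipeline, not soil ecology.
- Richness S is unrarefied pooled richness; with very uneven depths a
  rarefied variant would be preferable.
- The RMT scan uses global unfolding and a fixed bin set; on very small or
  very dense adjacency spectra it falls back conservatively (scan maximum
  with a warning).
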