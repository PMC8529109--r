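## synthetic_data: generate LinkedProfiles with the structure the analysis
## assumes -- long-tailed phylum abundances, genus diversity nested in phyla,
## and tunable cross-taxon functional redundancy.

#' Configure the synthetic soil-community generator
#'
#' The generator emulates a corpus of shotgun soil metagenomes: a few
#' dominant phyla and a long tail (geometrically decaying ranked phylum
#' abundances), genus-level taxa nested within phyla, per-genus functional
#' gene profiles that share a tunable core (functional redundancy), and
#' overdispersed counts (log-normal sample-to-sample noise on top of Poisson
#' sampling).
#'
#' @param nSamples number of metagenome samples.
#' @param nPhyla number of phyla; expected relative abundance of the rank-r
#'   phylum is proportional to `phylumDecay^r`.
#' @param generaPerPhylum genera simulated within each phylum.
#' @param nFunctions number of function-level categories; the three upper
#'   Subsystems-style levels are built deterministically on top (pairs of
#'   functions per level 3, pairs of level 3 per level 2, triples of level 2
#'   per level 1).
#' @param redundancy weight rho in \[0, 1\] of the shared core gene profile:
#'   each genus g uses `rho * pi_core + (1 - rho) * pi_g`, both symmetric
#'   Dirichlet(0.5) draws over functions. At rho = 1 every genus encodes the
#'   identical function profile (full functional redundancy).
#' @param phylumDecay geometric decay rate in (0, 1) for ranked phylum
#'   abundances.
#' @param depth expected total hits per sample.
#' @param dispersion sigma of the i.i.d. log-normal multiplicative noise
#'   applied per (sample, genus) before renormalization.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSamples = 40, nPhyla = 10, generaPerPhylum = 8,
                            nFunctions = 50, redundancy = 0.9,
                            phylumDecay = 0.5, depth = 1e5, dispersion = 0.5,
                            seed = 1) {
  new("SyntheticConfig",
      nSamples = as.integer(nSamples), nPhyla = as.integer(nPhyla),
      generaPerPhylum = as.integer(generaPerPhylum),
      nFunctions = as.integer(nFunctions),
      redundancy = as.numeric(redundancy),
      phylumDecay = as.numeric(phylumDecay), depth = as.numeric(depth),
      dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

## Deterministic Subsystems-style lineage over function ids: functions pair
## into level-3 subsystems, level 3 pairs into level 2, level 2 triples into
## level-1 categories.
functionLineage <- function(nFunctions) {
  f <- seq_len(nFunctions)
  l3 <- ceiling(f / 2)
  l2 <- ceiling(l3 / 2)
  l1 <- ceiling(l2 / 3)
  data.frame(
    function_id = sprintf("Fun%03d", f),
    level3 = sprintf("L3_%03d", l3),
    level2 = sprintf("L2_%02d", l2),
    level1 = sprintf("Category%02d", l1),
    stringsAsFactors = FALSE)
}

rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  if (all(g == 0)) g <- rep(1, k)  # guard against underflow at tiny alpha
  g / sum(g)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## Latent quantities shared by generateCommunity() and groundTruth().
latentCommunity <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  withSeed(config@seed, {
    phyla <- sprintf("Phylum%02d", seq_len(config@nPhyla))
    phylum_share <- config@phylumDecay ^ seq_len(config@nPhyla)
    phylum_share <- phylum_share / sum(phylum_share)
    names(phylum_share) <- phyla

    genera <- as.vector(vapply(phyla, function(p)
      sprintf("Genus_%s_%02d", p, seq_len(config@generaPerPhylum)),
      character(config@generaPerPhylum)))
    genus_phylum <- rep(phyla, each = config@generaPerPhylum)

    # genus shares within each phylum: symmetric Dirichlet(1)
    within <- as.vector(vapply(phyla, function(p)
      rdirichlet1(config@generaPerPhylum, 1), numeric(config@generaPerPhylum)))
    genus_share <- within * phylum_share[genus_phylum]
    names(genus_share) <- genera

    # per-genus function profiles: rho * core + (1 - rho) * specific
    core <- rdirichlet1(config@nFunctions, 0.5)
    profiles <- t(vapply(genera, function(g)
      config@redundancy * core +
        (1 - config@redundancy) * rdirichlet1(config@nFunctions, 0.5),
      numeric(config@nFunctions)))
    lineage <- functionLineage(config@nFunctions)
    colnames(profiles) <- lineage$function_id

    list(phyla = phyla, phylumShare = phylum_share, genera = genera,
         genusPhylum = setNames(genus_phylum, genera),
         genusShare = genus_share, core = setNames(core, lineage$function_id),
         profiles = profiles, lineage = lineage)
  })
}

#' Generate a synthetic joint taxonomy x function community
#'
#' Fixed generative contract: (1) phylum relative abundances proportional to
#' `phylumDecay^rank`; (2) genus shares within a phylum from a symmetric
#' Dirichlet(1); (3) genus g's function profile is
#' `rho * pi_core + (1 - rho) * pi_g`, both symmetric Dirichlet(0.5) over
#' functions, with one core draw shared by all genera; (4) per sample, genus
#' abundances are perturbed by i.i.d. log-normal(0, dispersion) factors and
#' renormalized; (5) hits for (sample, genus, function) are Poisson with mean
#' `depth * genus_abundance * pi_g[function]`. Deterministic given
#' `config@seed`; the global RNG state is left untouched.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [LinkedProfile-class]; zero-hit cells are omitted from the
#'   record set.
#' @seealso [groundTruth()] for the latent quantities behind the draw.
#' @export
generateCommunity <- function(config) {
  lat <- latentCommunity(config)
  n_gen <- length(lat$genera)
  n_fun <- config@nFunctions
  withSeed(config@seed + 1L, {
    samples <- sprintf("S%03d", seq_len(config@nSamples))
    rec <- vector("list", config@nSamples)
    for (s in seq_len(config@nSamples)) {
      noise <- rlnorm(n_gen, 0, config@dispersion)
      ab <- lat$genusShare * noise
      ab <- ab / sum(ab)
      lambda <- config@depth * ab * lat$profiles  # recycles ab down columns
      hits <- rpois(n_gen * n_fun, as.vector(lambda))
      keep <- hits > 0
      if (!any(keep)) next
      idx <- arrayInd(which(keep), c(n_gen, n_fun))
      rec[[s]] <- data.frame(
        sample = samples[s],
        genus = lat$genera[idx[, 1]],
        function_id = lat$lineage$function_id[idx[, 2]],
        hits = hits[keep],
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rec)
    rec$phylum <- unname(lat$genusPhylum[rec$genus])
    fm <- lat$lineage
    rec <- merge(rec, fm, by = "function_id", sort = FALSE)
    linkedProfile(rec[REQUIRED_COLUMNS], samples = samples)
  })
}

#' Latent ground truth of a synthetic community
#'
#' Returns the generator's latent quantities so tests can assert recovery:
#' the expected phylum ranking, within-phylum genus shares, the shared core
#' function profile and each genus's mixed profile.
#'
#' @param config a [SyntheticConfig-class].
#' @return a list with `phylumShare` (named, strictly descending by rank),
#'   `phylumRanking`, `genusShare`, `genusPhylum`, `coreProfile`,
#'   `functionProfiles` (genera x functions) and `lineage`.
#' @export
groundTruth <- function(config) {
  lat <- latentCommunity(config)
  list(phylumShare = lat$phylumShare,
       phylumRanking = names(sort(lat$phylumShare, decreasing = TRUE)),
       genusShare = lat$genusShare,
       genusPhylum = lat$genusPhylum,
       coreProfile = lat$core,
       functionProfiles = lat$profiles,
       lineage = lat$lineage)
}
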