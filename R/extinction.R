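## extinction: directed, abundance-ordered sequential species loss.
## Phyla are ranked by pooled relative abundance; each loss level retains the
## top-k phyla and filters the joint profile, so the functional hits of
## removed taxa disappear together with their taxa (the joint-key contract).

#' Rank phyla by pooled relative abundance, descending
#'
#' The ranking is global: hits are pooled over all samples before ranking,
#' defining one shared loss-level design for the whole corpus. Ties are
#' broken lexicographically by phylum name.
#'
#' @param profile a non-empty [LinkedProfile-class].
#' @return character vector of phylum names, most abundant first.
#' @export
rankPhyla <- function(profile) {
  stopifnot(is(profile, "LinkedProfile"))
  rec <- profileRecords(profile)
  if (!nrow(rec)) stop("cannot rank phyla of an empty profile")
  pooled <- tapply(rec$hits, rec$phylum, sum)
  names(pooled)[order(-pooled, names(pooled))]
}

#' Build nested loss levels from a phylum ranking
#'
#' Level k retains the top `sizes[k]` phyla; nesting is guaranteed because
#' `sizes` must be strictly decreasing. Levels are named by the retained
#' phylum count, with the classic All/Eight/Five/Two/One names where they
#' apply.
#'
#' @param ranking ordered phylum vector from [rankPhyla()].
#' @param sizes strictly decreasing retained-phylum counts; defaults to the
#'   full count followed by 8, 5, 2, 1 (clipped to the available phyla).
#' @return list of [LossLevel-class] objects.
#' @export
defaultLevels <- function(ranking, sizes = NULL) {
  n <- length(ranking)
  if (is.null(sizes)) sizes <- unique(c(n, c(8L, 5L, 2L, 1L)[c(8L, 5L, 2L, 1L) < n]))
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 1))
    stop("sizes must be positive integers")
  if (any(diff(sizes) >= 0))
    stop("sizes must be strictly decreasing")
  if (max(sizes) > n)
    stop("largest size exceeds the number of ranked phyla")
  classic <- c("1" = "One", "2" = "Two", "5" = "Five", "8" = "Eight")
  lapply(sizes, function(k) {
    nm <- if (k == n) "All"
          else if (as.character(k) %in% names(classic)) classic[[as.character(k)]]
          else as.character(k)
    new("LossLevel", name = nm, retainedPhyla = ranking[seq_len(k)])
  })
}

#' Filter a joint profile to one loss level's retained phyla
#'
#' Keeps only records whose genus maps to a retained phylum. Because records
#' carry the joint (genus, function) key, both the taxonomy projection and
#' the function projection of the result reflect the filter.
#'
#' @param profile a [LinkedProfile-class].
#' @param level a [LossLevel-class]. Retained phyla absent from the profile
#'   warn but do not fail.
#' @return the filtered [LinkedProfile-class] (sample list unchanged).
#' @export
applyLossLevel <- function(profile, level) {
  stopifnot(is(profile, "LinkedProfile"), is(level, "LossLevel"))
  present <- unique(unname(taxonomyMap(profile)))
  absent <- setdiff(level@retainedPhyla, present)
  if (length(absent))
    warning("retained phylum/a not present in profile: ",
            paste(absent, collapse = ", "))
  rec <- profileRecords(profile)
  keep <- rec$phylum %in% level@retainedPhyla
  if (!any(keep))
    warning(sprintf("loss level '%s' retains no hits; empty profile returned",
                    level@name))
  linkedProfile(rec[keep, , drop = FALSE], samples = sampleIds(profile))
}

#' Run the full directed loss series and report S/N reductions
#'
#' For each nested level the profile is filtered, projected to the
#' genus-level taxonomy table and the function-level function table (counts
#' and relative abundance), and summarized into species (S) and individuals
#' (N) with percent reductions relative to the full community. When three or
#' more levels are present, Pearson r-squared of S and N against the level
#' index quantifies the linearity of the decline.
#'
#' @param profile a [LinkedProfile-class].
#' @param levels list of nested [LossLevel-class] objects (each later set a
#'   subset of the earlier one); violations raise an error.
#' @return a [LossSeriesReport-class].
#' @export
lossSeries <- function(profile, levels) {
  stopifnot(is(profile, "LinkedProfile"), is.list(levels), length(levels) >= 1)
  for (i in seq_along(levels)[-1]) {
    if (!all(levels[[i]]@retainedPhyla %in% levels[[i - 1]]@retainedPhyla))
      stop(sprintf("levels not nested: '%s' is not a subset of '%s'",
                   levels[[i]]@name, levels[[i - 1]]@name))
  }
  level_names <- vapply(levels, function(l) l@name, character(1))
  tables <- setNames(vector("list", length(levels)), level_names)
  rows <- list()
  base <- list()
  for (i in seq_along(levels)) {
    filtered <- suppressWarnings(applyLossLevel(profile, levels[[i]]))
    tab <- list(
      taxonomy = projectProfile(filtered, "taxonomy", "genus"),
      func = projectProfile(filtered, "function", "function"))
    tab$taxonomyRelative <- suppressWarnings(toRelativeAbundance(tab$taxonomy))
    tab$funcRelative <- suppressWarnings(toRelativeAbundance(tab$func))
    tables[[i]] <- tab
    for (kind in c("taxonomy", "function")) {
      cs <- communitySummary(if (kind == "taxonomy") tab$taxonomy else tab$func)
      if (i == 1) base[[kind]] <- cs
      rows[[length(rows) + 1]] <- data.frame(
        level = level_names[i], kind = kind, index = i,
        retained_phyla = length(levels[[i]]@retainedPhyla),
        S = cs@S, N = cs@N,
        pct_reduction_S = if (base[[kind]]@S > 0)
          100 * (1 - cs@S / base[[kind]]@S) else 0,
        pct_reduction_N = if (base[[kind]]@N > 0)
          100 * (1 - cs@N / base[[kind]]@N) else 0,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$index, summary$kind), ]
  correlations <- list()
  if (length(levels) >= 3) {
    for (kind in c("taxonomy", "function")) {
      sub <- summary[summary$kind == kind, ]
      for (stat in c("S", "N")) {
        y <- sub[[stat]]
        if (var(y) > 0)
          correlations[[paste(kind, stat, sep = "_")]] <-
            pearsonCorrelation(sub$index, y)
      }
    }
  }
  new("LossSeriesReport", summary = summary, tables = tables,
      correlations = correlations)
}
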