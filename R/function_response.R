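## function_response: per-category abundance trends across loss levels,
## one-way ANOVA F per category, within-category renormalized PERMANOVA,
## abundance-response correlation, and Spearman/UPGMA heatmap clustering.

#' Mean relative abundance of level-1 function categories per loss level
#'
#' @param functionTables named list (one entry per loss level, in series
#'   order) of level-1 [AbundanceTable-class]s in relative abundance. Tables
#'   with differing category universes are reconciled by union with zeros
#'   (reported via a message).
#' @param dominanceCutoff categories whose overall mean relative abundance
#'   exceeds this fraction are flagged dominant (1% by default; the
#'   function-specific panel conventionally uses 0.5%).
#' @return data.frame: `category`, one `mean_<level>` column per level,
#'   `overall_mean`, `dominant`; rows sorted by descending overall mean.
#' @export
categoryTrends <- function(functionTables, dominanceCutoff = 0.01) {
  stopifnot(is.list(functionTables), length(functionTables) >= 1)
  mats <- lapply(functionTables, asMatrixInput)
  universe <- sort(unique(unlist(lapply(mats, colnames))))
  if (!all(vapply(mats, function(m) identical(sort(colnames(m)), universe),
                  logical(1))))
    message("category universes differ across levels; reconciled by union")
  levels_ <- names(functionTables)
  if (is.null(levels_)) levels_ <- paste0("level", seq_along(functionTables))
  means <- vapply(mats, function(m) {
    full <- setNames(numeric(length(universe)), universe)
    full[colnames(m)] <- colMeans(m)
    full
  }, numeric(length(universe)))
  colnames(means) <- paste0("mean_", levels_)
  overall <- rowMeans(means)
  out <- data.frame(category = universe, means, overall_mean = overall,
                    dominant = overall > dominanceCutoff,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out[order(-out$overall_mean), , drop = FALSE]
}

#' One-way ANOVA F per function category
#'
#' Classical one-way ANOVA of each category's per-sample relative abundance
#' with loss level as the single factor. A category with zero between- and
#' within-group variance has no defined F and is reported as `NA`.
#'
#' @param values samples x categories matrix (or [AbundanceTable-class]) of
#'   relative abundances, rows aligned with `groups`.
#' @param groups loss-level label per sample; >= 2 levels with >= 2 samples
#'   each.
#' @return data.frame: `category`, `F`, `df1`, `df2`, `p`.
#' @export
anovaPerCategory <- function(values, groups) {
  x <- asMatrixInput(values)
  groups <- as.factor(groups)
  if (nrow(x) != length(groups)) stop("groups length must match sample count")
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 levels with >= 2 samples each")
  res <- lapply(colnames(x), function(cat) {
    y <- x[, cat]
    if (var(y) == 0)
      return(data.frame(category = cat, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_))
    tab <- anova(lm(y ~ groups))
    data.frame(category = cat, F = tab$`F value`[1], df1 = tab$Df[1],
               df2 = tab$Df[2], p = tab$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Within-category renormalized PERMANOVA
#'
#' For each level-1 category with at least two member functions, the member
#' functions' hits are renormalized to sum to one within the category per
#' sample (so only the category's internal composition matters, not its
#' overall abundance), then Bray-Curtis + one-factor PERMANOVA against the
#' loss-level factor. Single-function categories are skipped with a message.
#'
#' @param functionTable function-level [AbundanceTable-class] (samples x
#'   functions; counts or relative abundance -- renormalization makes them
#'   equivalent), rows aligned with `groups`.
#' @param lineage data.frame mapping `function_id` to `level1` (as from
#'   `functionMap()` plus rownames, or `groundTruth()$lineage`).
#' @param groups loss-level label per sample.
#' @inheritParams permanova
#' @return data.frame: `category`, `n_functions`, `pseudo_F`, `R2`, `p`.
#' @export
withinCategoryPermanova <- function(functionTable, lineage, groups,
                                    nPermutations = 999, seed = 1) {
  x <- asMatrixInput(functionTable)
  if (!all(c("function_id", "level1") %in% names(lineage)))
    stop("lineage needs columns 'function_id' and 'level1'")
  cat_of <- setNames(lineage$level1, lineage$function_id)
  known <- colnames(x)[colnames(x) %in% names(cat_of)]
  cats <- sort(unique(unname(cat_of[known])))
  out <- list()
  for (ct in cats) {
    members <- known[cat_of[known] == ct]
    if (length(members) < 2) {
      message(sprintf("category '%s' has a single member function; skipped", ct))
      next
    }
    sub <- x[, members, drop = FALSE]
    keep <- rowSums(sub) > 0
    if (sum(keep) < 4 || nlevels(droplevels(as.factor(groups[keep]))) < 2) {
      message(sprintf("category '%s' has too few non-empty samples; skipped", ct))
      next
    }
    d <- suppressMessages(brayCurtis(sub[keep, , drop = FALSE],
                                     relative = TRUE))
    res <- tryCatch(
      permanova(d, groups[keep], nPermutations = nPermutations, seed = seed),
      error = function(e) NULL)
    if (is.null(res)) next
    out[[ct]] <- data.frame(category = ct, n_functions = length(members),
                            pseudo_F = res@pseudoF, R2 = res@R2, p = res@p,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(category = character(), n_functions = integer(),
                      pseudo_F = numeric(), R2 = numeric(), p = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlate a response statistic with category abundance
#'
#' Pearson correlation, across dominant categories, between a per-category
#' response statistic (one-way ANOVA F or within-category pseudo-F) and the
#' category's mean relative abundance.
#'
#' @param abundance named numeric vector of mean relative abundance per
#'   category (e.g. `overall_mean` from [categoryTrends()]).
#' @param statistic named numeric vector of the chosen statistic per
#'   category; matched to `abundance` by name, categories missing from
#'   either side dropped.
#' @return a [CorrelationResult-class]; `@n` is the number of categories
#'   correlated.
#' @export
abundanceResponseCorrelation <- function(abundance, statistic) {
  shared <- intersect(names(abundance), names(statistic))
  shared <- shared[!is.na(abundance[shared]) & !is.na(statistic[shared])]
  if (length(shared) < 3) stop("need >= 3 categories with both values")
  pearsonCorrelation(unname(abundance[shared]), unname(statistic[shared]))
}

#' Spearman-distance UPGMA clustering of the category x level matrix
#'
#' Rows (categories) are z-scored across loss levels, the distance between
#' rows is `1 - Spearman rank correlation` (average ranks on ties), and rows
#' are clustered by average linkage (UPGMA). Constant rows have no defined
#' rank correlation; they are flagged and assigned the maximal distance 2 to
#' every other row. Leaf order is deterministic.
#'
#' @param mat categories x levels numeric matrix (>= 2 rows and columns),
#'   e.g. the `mean_*` columns of [categoryTrends()].
#' @return a [HeatmapResult-class].
#' @export
heatmapCluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 categories and 2 levels")
  rsd <- apply(mat, 1, sd)
  constant <- rownames(mat)[rsd == 0]
  if (is.null(constant)) constant <- character()
  z <- mat
  nz <- rsd > 0
  z[nz, ] <- (mat[nz, , drop = FALSE] - rowMeans(mat[nz, , drop = FALSE])) /
    rsd[nz]
  z[!nz, ] <- 0
  ranks <- t(apply(mat, 1, rank, ties.method = "average"))
  D <- matrix(2, nrow(mat), nrow(mat), dimnames = list(rownames(mat),
                                                       rownames(mat)))
  if (any(nz)) {
    rc <- suppressWarnings(cor(t(ranks[nz, , drop = FALSE])))
    D[nz, nz] <- 1 - rc
  }
  diag(D) <- 0
  if (length(constant))
    message("constant row(s) assigned maximal Spearman distance: ",
            paste(constant, collapse = ", "))
  hc <- hclust(as.dist(D), method = "average")
  new("HeatmapResult", matrix = z, rowOrder = as.integer(hc$order),
      linkage = hc, constantRows = constant)
}

setMethod("show", "HeatmapResult", function(object) {
  cat(sprintf("HeatmapResult: %d categories x %d levels; leaf order: %s\n",
              nrow(object@matrix), ncol(object@matrix),
              paste(rownames(object@matrix)[object@rowOrder],
                    collapse = ", ")))
})
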