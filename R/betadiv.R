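## betadiv: from-scratch multivariate statistics.
## Bray-Curtis dissimilarity, principal coordinates analysis, PERMANOVA
## (main and pairwise permutation tests) and Pearson correlation are authored
## here; they are the analytical core of the loss-series comparison.

asMatrixInput <- function(table) {
  if (is(table, "AbundanceTable")) table@.Data else as.matrix(table)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `D_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`; the field reports the
#' complementary similarity as `100 * (1 - D)` percent. A pair in which both
#' rows are all zero has no defined numerator share and is set to `D = 0` by
#' convention (reported via a message).
#'
#' @param table an [AbundanceTable-class] or numeric matrix, samples in rows,
#'   values >= 0; at least two samples.
#' @param relative if `TRUE` (default) rows are first normalized to relative
#'   abundance, matching the standard treatment of metagenome hit counts.
#' @return a [stats::dist] object with sample labels.
#' @export
brayCurtis <- function(table, relative = TRUE) {
  x <- asMatrixInput(table)
  if (nrow(x) < 2) stop("Bray-Curtis needs at least two samples")
  if (any(x < 0)) stop("abundances must be non-negative")
  if (relative) {
    tot <- rowSums(x)
    nz <- tot > 0
    x[nz, ] <- x[nz, , drop = FALSE] / tot[nz]
  }
  num <- as.matrix(dist(x, method = "manhattan"))
  tot <- rowSums(x)
  den <- outer(tot, tot, "+")
  D <- matrix(0, nrow(x), nrow(x), dimnames = dimnames(num))
  ok <- den > 0
  D[ok] <- num[ok] / den[ok]
  if (any(!ok & upper.tri(den)))
    message("pair(s) of all-zero samples assigned D = 0 by convention")
  as.dist(D)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of `-0.5 * D^2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by
#' `sqrt(max(eigenvalue, 0))`; axes are ordered by descending eigenvalue and
#' their sign is fixed by forcing the largest-magnitude loading per axis
#' positive, so output is deterministic. Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are retained in
#' `@eigenvalues` but excluded from the percent-variation denominator.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix.
#' @param nAxes number of axes to return; clipped to n - 1 with a warning.
#' @return a [PcoaResult-class].
#' @export
pcoa <- function(d, nAxes = 2) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop("PCoA needs at least two samples")
  if (nAxes > n - 1) {
    warning(sprintf("nAxes clipped from %d to %d", nAxes, n - 1))
    nAxes <- n - 1
  }
  A <- -0.5 * D * D
  G <- A - rowMeans(A)          # row centering
  G <- t(t(G) - colMeans(G))    # then column centering completes Gower
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  k <- seq_len(nAxes)
  coords <- vectors[, k, drop = FALSE] %*% diag(sqrt(pmax(values[k], 0)),
                                                nrow = length(k))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", k)
  pos <- values[values > 1e-12]
  pv <- if (length(pos)) 100 * pmax(values[k], 0) / sum(pos) else rep(0, nAxes)
  new("PcoaResult", coordinates = coords, eigenvalues = values,
      percentVariation = pv)
}

## Sum-of-squares partition of a squared-distance matrix for one labeling.
## Returns c(F, R2); groups given as an integer indicator matrix is avoided:
## we need this inside a tight permutation loop.
permanovaStats <- function(D2, groupIdx, nGroups, groupSizes, N) {
  ssTotal <- sum(D2) / (2 * N)
  within <- numeric(nGroups)
  for (g in seq_len(nGroups)) {
    idx <- groupIdx[[g]]
    within[g] <- sum(D2[idx, idx]) / (2 * groupSizes[g])
  }
  ssWithin <- sum(within)
  ssBetween <- ssTotal - ssWithin
  f <- (ssBetween / (nGroups - 1)) / (ssWithin / (N - nGroups))
  c(F = f, R2 = ssBetween / ssTotal, ssWithin = ssWithin)
}

#' One-factor PERMANOVA (permutational multivariate ANOVA)
#'
#' Partitions the squared-dissimilarity sums of squares among groups:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo-F = (SS_between / (a-1)) / (SS_within / (N-a))`, with a
#' permutation p-value `(1 + b) / (1 + m)` where `b` counts permuted
#' statistics at or above the observed one. Group labels are permuted
#' unrestrictedly by default; pass `strata` to restrict shuffling to within
#' blocks (e.g. repeated measures of the same metagenome across loss
#' levels).
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param nPermutations Monte-Carlo permutations (>= 1), default 999.
#' @param seed RNG seed for the permutation draw; runs are bit-reproducible.
#' @param strata optional blocking factor; labels are permuted only within
#'   blocks.
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(d, groups, nPermutations = 999, seed = 1,
                      strata = NULL) {
  D2 <- as.matrix(d)
  D2 <- D2 * D2
  N <- nrow(D2)
  groups <- as.factor(groups)
  if (length(groups) != N) stop("groups length must match the matrix size")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("PERMANOVA needs at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two samples")
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  a <- length(sizes)
  gi <- split(seq_len(N), groups)
  obs <- permanovaStats(D2, gi, a, as.numeric(sizes), N)
  if (obs[["ssWithin"]] <= 0 && !is.finite(obs[["F"]]))
    stop("undefined statistic: within-group sum of squares is zero")
  glab <- as.integer(groups)
  exceed <- 0L
  tol <- 1e-8 * max(1, abs(obs[["F"]]))
  withSeed(seed, {
    if (!is.null(strata)) {
      strata <- as.factor(strata)
      sidx <- split(seq_len(N), strata)
    }
    for (b in seq_len(nPermutations)) {
      perm <- if (is.null(strata)) sample.int(N) else {
        p <- integer(N)
        for (s in sidx) p[s] <- s[sample.int(length(s))]
        p
      }
      pg <- split(seq_len(N), glab[perm])
      fp <- permanovaStats(D2, pg, a, as.numeric(sizes), N)[["F"]]
      if (fp >= obs[["F"]] - tol) exceed <- exceed + 1L
    }
  })
  new("PermanovaResult", pseudoF = unname(obs[["F"]]),
      dfBetween = a - 1, dfWithin = N - a,
      p = (1 + exceed) / (1 + nPermutations),
      R2 = unname(obs[["R2"]]), nPermutations = nPermutations, seed = seed)
}

#' Pairwise PERMANOVA comparisons (pseudo-t)
#'
#' Runs the two-group PERMANOVA on each unordered group pair's sub-matrix
#' and reports `pseudo-t = sqrt(pseudo-F)`. Unadjusted p-values by default
#' (PRIMER-style reporting); set `adjust` to any [stats::p.adjust] method for
#' a corrected column.
#'
#' @inheritParams permanova
#' @param adjust multiplicity adjustment method, default `"none"`.
#' @return data.frame with columns `group_a`, `group_b`, `pseudo_t`,
#'   `pseudo_F`, `p` (and `p_adjusted` unless `adjust = "none"`).
#' @export
permanovaPairwise <- function(d, groups, nPermutations = 999, seed = 1,
                              adjust = "none") {
  D <- as.matrix(d)
  groups <- as.factor(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    idx <- which(groups %in% c(ga, gb))
    res <- permanova(as.dist(D[idx, idx, drop = FALSE]),
                     droplevels(groups[idx]), nPermutations,
                     seed = seed + k - 1)
    out[[k]] <- data.frame(group_a = ga, group_b = gb,
                           pseudo_t = sqrt(res@pseudoF),
                           pseudo_F = res@pseudoF, p = res@p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (adjust != "none") out$p_adjusted <- p.adjust(out$p, method = adjust)
  out
}

#' Pearson product-moment correlation with t-approximation p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return a [CorrelationResult-class] with `r`, `r2`, two-sided `p` from
#'   `t = r * sqrt((n - 2) / (1 - r^2))`, and `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  new("CorrelationResult", r = r, r2 = r^2, p = p, n = n)
}

#' Mean pairwise Bray-Curtis similarity, in percent
#'
#' Convenience summary used in the loss-series report: the across-pair mean
#' of `100 * (1 - D)`.
#'
#' @param d a [stats::dist] of Bray-Curtis dissimilarities.
#' @return a single number in \[0, 100\].
#' @export
meanSimilarityPct <- function(d) {
  mean(100 * (1 - as.numeric(d)))
}
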