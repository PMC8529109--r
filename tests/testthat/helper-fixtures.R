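# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# A minimal joint record table: sample x genus x function long rows.
toyRecords <- function() {
  data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    genus = c("g1", "g1", "g2", "g1", "g2", "g3"),
    phylum = c("P1", "P1", "P2", "P1", "P2", "P3"),
    function_id = c("f1", "f2", "f1", "f1", "f2", "f2"),
    level1 = c("A", "B", "A", "A", "B", "B"),
    level2 = c("A2", "B2", "A2", "A2", "B2", "B2"),
    level3 = c("A3", "B3", "A3", "A3", "B3", "B3"),
    hits = c(5, 3, 2, 4, 1, 6),
    stringsAsFactors = FALSE)
}

toyProfile <- function() linkedProfile(toyRecords())

# Symmetric correlation matrix from an (i, j, r) triplet list.
corrFromPairs <- function(pairs, ids) {
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- p[[3]]
    m[p[[2]], p[[1]]] <- p[[3]]
  }
  m
}

# Brute-force Bray-Curtis between two numeric vectors.
bcPair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Independent brute-force PERMANOVA statistic from first principles:
# double loops over pairs, no shared code with the package implementation.
bruteForcePermanova <- function(D, groups) {
  N <- nrow(D)
  groups <- as.character(groups)
  ssTotal <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssTotal <- ssTotal + D[i, j]^2
  ssTotal <- ssTotal / N
  ssWithin <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + D[idx[a], idx[b]]^2
    ssWithin <- ssWithin + acc / length(idx)
  }
  a <- length(unique(groups))
  ssBetween <- ssTotal - ssWithin
  list(F = (ssBetween / (a - 1)) / (ssWithin / (N - a)),
       R2 = ssBetween / ssTotal)
}
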