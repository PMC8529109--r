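test_that("Bray-Curtis matches hand arithmetic and stays bounded", {
  x <- matrix(c(0.7, 0.3, 0,
                0.3, 0.3, 0.4), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  d <- brayCurtis(x, relative = FALSE)
  expect_equal(as.numeric(d), 0.4)          # 0.8 / 2, similarity 60%
  expect_equal(meanSimilarityPct(d), 60)

  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.numeric(brayCurtis(same, relative = FALSE)), 0)
  disjoint <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 2, 2))
  expect_equal(as.numeric(brayCurtis(disjoint, relative = FALSE)), 1)

  expect_error(brayCurtis(matrix(1, 1, 3)), "two samples")
  set.seed(4)
  m <- matrix(rexp(48), 8, 6)
  D <- as.matrix(brayCurtis(m))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
})

test_that("Bray-Curtis handles all-zero sample pairs by the D = 0 convention", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_message(d <- brayCurtis(m, relative = TRUE), "convention")
  expect_equal(as.matrix(d)["a", "b"], 0)
  expect_equal(as.matrix(d)["a", "c"], 1)
})

test_that("Bray-Curtis agrees with the vegan oracle on random tables", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:3) {
    m <- matrix(rpois(60, 8), 6, 10)
    rownames(m) <- paste0("s", 1:6)
    mine <- brayCurtis(m, relative = TRUE)
    rel <- m / rowSums(m)
    ref <- vegan::vegdist(rel, method = "bray")
    expect_equal(as.numeric(mine), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("PCoA reproduces analytic configurations", {
  # two points at D = 0.5: coordinates +/- 0.25 on one positive axis
  d2 <- as.dist(matrix(c(0, 0.5, 0.5, 0), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  r2 <- pcoa(d2, nAxes = 1)
  expect_equal(sort(as.numeric(r2@coordinates)), c(-0.25, 0.25))
  expect_equal(sum(r2@eigenvalues > 1e-12), 1)

  # three equidistant points: two equal positive eigenvalues, 50/50 split
  d3 <- as.dist(matrix(1, 3, 3) - diag(3))
  r3 <- pcoa(d3, nAxes = 2)
  pos <- r3@eigenvalues[r3@eigenvalues > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  expect_equal(r3@percentVariation, c(50, 50), tolerance = 1e-9)
})

test_that("PCoA on Euclidean distances recovers the configuration", {
  set.seed(17)
  pts <- matrix(rnorm(60), 30, 2)
  res <- pcoa(dist(pts), nAxes = 2)
  # align by orthogonal Procrustes (both centered): rotation from SVD
  X <- scale(pts, scale = FALSE)
  Y <- res@coordinates
  s <- svd(crossprod(X, Y))
  rot <- Y %*% s$v %*% t(s$u)
  expect_lt(sqrt(mean((rot - X)^2)), 1e-8)
  # Euclidean input: no meaningfully negative eigenvalue
  expect_gt(min(res@eigenvalues), -1e-9)
  # percent variation over positive axes sums to 100
  all_axes <- pcoa(dist(pts), nAxes = 29)
  pv <- all_axes@percentVariation[all_axes@eigenvalues[1:29] > 1e-12]
  expect_equal(sum(pv), 100, tolerance = 1e-6)
})

test_that("PCoA axis count is clipped with a warning and signs are fixed", {
  d <- dist(matrix(rnorm(12), 4, 3))
  expect_warning(r <- pcoa(d, nAxes = 10), "clipped")
  expect_equal(ncol(r@coordinates), 3)
  for (j in seq_len(ncol(r@coordinates))) {
    v <- r@coordinates[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
})

test_that("PERMANOVA partitions sums of squares and matches brute force", {
  set.seed(23)
  m <- matrix(rexp(50), 10, 5)
  rownames(m) <- paste0("s", 1:10)
  g <- rep(c("x", "y"), each = 5)
  d <- brayCurtis(m)
  res <- permanova(d, g, nPermutations = 99, seed = 1)
  oracle <- bruteForcePermanova(as.matrix(d), g)
  expect_equal(res@pseudoF, oracle$F, tolerance = 1e-12)
  expect_equal(res@R2, oracle$R2, tolerance = 1e-12)
  expect_equal(res@dfBetween, 1)
  expect_equal(res@dfWithin, 8)
  # p bounded by the permutation-count floor
  expect_gte(res@p, 1 / 100)
  expect_lte(res@p, 1)
})

test_that("PERMANOVA equals classical one-way ANOVA on univariate data", {
  set.seed(29)
  for (rep in 1:10) {
    y <- rnorm(15)
    g <- rep(c("a", "b", "c"), each = 5)
    res <- permanova(dist(y), g, nPermutations = 1, seed = 1)
    f_aov <- anova(lm(y ~ g))$`F value`[1]
    expect_equal(res@pseudoF, f_aov, tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(rpois(120, 6), 12, 10)
  rownames(m) <- paste0("s", 1:12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- brayCurtis(m)
  res <- permanova(d, g, nPermutations = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res@pseudoF, ref$F[1], tolerance = 1e-10)
  expect_equal(res@R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA statistic is invariant under within-group relabeling", {
  set.seed(37)
  m <- matrix(rexp(60), 12, 5)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(brayCurtis(m))
  f0 <- permanova(as.dist(d), g, 1, seed = 1)@pseudoF
  perm <- c(4:1, 8:5, 12:9)   # permutes samples within their groups
  f1 <- permanova(as.dist(d[perm, perm]), g, 1, seed = 1)@pseudoF
  expect_equal(f0, f1, tolerance = 1e-12)
})

test_that("PERMANOVA rejects degenerate designs", {
  d <- dist(1:6)
  expect_error(permanova(d, rep("a", 6)), "two groups")
  expect_error(permanova(d, c("a", rep("b", 5))), "at least two samples")
  zero <- as.dist(matrix(0, 6, 6))
  expect_error(permanova(zero, rep(c("a", "b"), each = 3)), "undefined")
})

test_that("seeded PERMANOVA runs are bit-reproducible", {
  set.seed(41)
  m <- matrix(rexp(60), 12, 5)
  g <- rep(c("a", "b"), each = 6)
  d <- brayCurtis(m)
  r1 <- permanova(d, g, 199, seed = 7)
  r2 <- permanova(d, g, 199, seed = 7)
  expect_identical(r1@p, r2@p)
})

test_that("blocked permutation restricts shuffling to within strata", {
  # one strongly blocked dataset: with strata the treatment labels only
  # permute within subjects, so the p-value differs from unrestricted
  set.seed(43)
  subj <- rep(1:6, each = 2)
  treat <- rep(c("t1", "t2"), 6)
  y <- rnorm(12, mean = ifelse(treat == "t2", 2, 0)) + rep(rnorm(6, sd = 3), each = 2)
  d <- dist(y)
  r_block <- permanova(d, treat, 499, seed = 1, strata = subj)
  expect_lt(r_block@p, 0.2)   # blocking removes the subject noise
  expect_s4_class(r_block, "PermanovaResult")
})

test_that("pairwise tests satisfy pseudo-t = sqrt(pseudo-F) and match sub-matrices", {
  set.seed(47)
  m <- matrix(rexp(90), 18, 5)
  rownames(m) <- paste0("s", 1:18)
  g <- rep(c("a", "b", "c"), each = 6)
  d <- brayCurtis(m)
  pw <- permanovaPairwise(d, g, nPermutations = 49, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$pseudo_t^2, pw$pseudo_F, tolerance = 1e-12)
  D <- as.matrix(d)
  for (k in seq_len(nrow(pw))) {
    idx <- which(g %in% c(pw$group_a[k], pw$group_b[k]))
    oracle <- bruteForcePermanova(D[idx, idx], g[idx])
    expect_equal(pw$pseudo_F[k], oracle$F, tolerance = 1e-12)
  }
  # duplicated groups with tiny jitter: null case, large p
  base <- matrix(rexp(30), 6, 5)
  dup <- rbind(base, base + matrix(rnorm(30, sd = 1e-4), 6, 5))
  dup[dup < 0] <- 0
  rownames(dup) <- paste0("s", 1:12)
  pw0 <- permanovaPairwise(brayCurtis(dup), rep(c("a", "b"), each = 6),
                           nPermutations = 199, seed = 3)
  expect_gt(pw0$p[1], 0.2)
  # multiplicity adjustment is available but off by default
  expect_false("p_adjusted" %in% names(pw))
  pw_adj <- permanovaPairwise(d, g, nPermutations = 49, seed = 5,
                              adjust = "holm")
  expect_true(all(pw_adj$p_adjusted >= pw_adj$p))
})

test_that("Pearson correlation matches hand values and the cor.test oracle", {
  perf <- pearsonCorrelation(1:10, 2 * (1:10) + 1)
  expect_equal(perf@r, 1)
  expect_equal(perf@r2, 1)
  expect_equal(perf@p, 0)

  orth <- pearsonCorrelation(c(1, 2, 3), c(1, -2, 1))   # orthogonal to trend
  expect_equal(orth@r, 0)
  expect_equal(orth@p, 1)

  hand <- pearsonCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hand@r, 0.6, tolerance = 1e-12)
  expect_equal(hand@r2, hand@r^2, tolerance = 1e-12)

  set.seed(53)
  x <- rnorm(20); y <- x + rnorm(20)
  mine <- pearsonCorrelation(x, y)
  ref <- cor.test(x, y)
  expect_equal(mine@r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine@p, ref$p.value, tolerance = 1e-10)

  expect_error(pearsonCorrelation(1:3, rep(1, 3)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
})
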