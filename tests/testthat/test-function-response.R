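test_that("category trends average per level and apply the dominance cutoff", {
  t1 <- new("AbundanceTable",
            matrix(c(0.6, 0.3, 0.1,
                     0.4, 0.5, 0.1), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
            kind = "function", level = "level1", relative = TRUE)
  t2 <- new("AbundanceTable",
            matrix(c(0.8, 0.2, 0,
                     0.6, 0.4, 0), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
            kind = "function", level = "level1", relative = TRUE)
  tr <- categoryTrends(list(All = t1, Two = t2), dominanceCutoff = 0.05)
  expect_equal(tr$`mean_All`[tr$category == "A"], 0.5)
  expect_equal(tr$`mean_Two`[tr$category == "A"], 0.7)
  expect_equal(tr$`mean_All`[tr$category == "B"], 0.4)
  expect_equal(tr$overall_mean[tr$category == "C"], 0.05)
  expect_identical(tr$dominant[match(c("A", "B", "C"), tr$category)],
                   c(TRUE, TRUE, FALSE))
  # rows ordered by descending overall mean
  expect_identical(tr$category, c("A", "B", "C"))
})

test_that("mismatched category universes are reconciled by union with zeros", {
  t1 <- new("AbundanceTable",
            matrix(c(1, 0.5), 2, 1, dimnames = list(c("s1", "s2"), "A")),
            kind = "function", level = "level1", relative = FALSE)
  t2 <- new("AbundanceTable",
            matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("s1", "s2"), "B")),
            kind = "function", level = "level1", relative = FALSE)
  expect_message(tr <- categoryTrends(list(a = t1, b = t2), 0.01),
                 "reconciled")
  expect_equal(tr$mean_b[tr$category == "A"], 0)
  expect_equal(tr$mean_a[tr$category == "B"], 0)
})

test_that("per-category ANOVA matches hand computation and the PERMANOVA limit", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("lo", "hi"), each = 3)
  res <- anovaPerCategory(matrix(y, 6, 1, dimnames = list(paste0("s", 1:6),
                                                          "cat")), g)
  expect_equal(res$F, 13.5, tolerance = 1e-12)   # hand one-way ANOVA
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)

  # equivalence: univariate Euclidean PERMANOVA pseudo-F equals ANOVA F
  pf <- permanova(dist(y), g, nPermutations = 1, seed = 1)@pseudoF
  expect_equal(res$F, pf, tolerance = 1e-10)

  # null case: identical groups give F near zero
  y0 <- rep(c(1, 2, 3), 2)
  res0 <- anovaPerCategory(matrix(y0, 6, 1, dimnames = list(paste0("s", 1:6),
                                                            "cat")),
                           rep(c("a", "b"), each = 3))
  expect_lt(res0$F, 1e-20)

  # degenerate: zero variance everywhere reported as missing
  resNA <- anovaPerCategory(matrix(1, 6, 1, dimnames = list(paste0("s", 1:6),
                                                            "cat")), g)
  expect_true(is.na(resNA$F))
})

test_that("within-category PERMANOVA sees only internal composition", {
  lineage <- data.frame(function_id = paste0("f", 1:4),
                        level1 = rep("CatA", 4), stringsAsFactors = FALSE)
  set.seed(61)
  base <- matrix(rexp(48, rate = 1) + 0.5, 12, 4,
                 dimnames = list(paste0("s", 1:12), paste0("f", 1:4)))
  g <- rep(c("a", "b"), each = 6)
  r1 <- withinCategoryPermanova(base, lineage, g, nPermutations = 99, seed = 2)
  # scaling all member functions by a common per-sample factor changes nothing
  scaled <- base * runif(12, 0.1, 10)
  r2 <- withinCategoryPermanova(scaled, lineage, g, nPermutations = 99, seed = 2)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)

  # single-function categories are skipped
  lin1 <- data.frame(function_id = "f1", level1 = "Solo",
                     stringsAsFactors = FALSE)
  expect_message(
    r3 <- withinCategoryPermanova(base[, 1, drop = FALSE], lin1, g, 9, 1),
    "single member")
  expect_equal(nrow(r3), 0)
})

test_that("a planted within-category shift yields that category's largest pseudo-F", {
  set.seed(67)
  nS <- 18
  g <- rep(c("All", "Five", "One"), each = 6)
  cats <- c("CatA", "CatB", "CatC")
  lineage <- data.frame(function_id = paste0("f", 1:12),
                        level1 = rep(cats, each = 4),
                        stringsAsFactors = FALSE)
  profs <- list(CatA = c(4, 3, 2, 1), CatB = c(1, 1, 1, 1),
                CatC = c(5, 2, 2, 1))
  x <- matrix(0, nS, 12, dimnames = list(paste0("s", 1:nS),
                                         lineage$function_id))
  for (ci in seq_along(cats)) {
    pr <- profs[[ci]]
    for (s in seq_len(nS)) {
      mix <- pr
      if (cats[ci] == "CatC" && g[s] == "One") mix <- rev(pr)  # planted shift
      x[s, lineage$level1 == cats[ci]] <-
        mix * exp(rnorm(4, sd = 0.15)) # mild multiplicative noise
    }
  }
  res <- withinCategoryPermanova(x, lineage, g, nPermutations = 99, seed = 3)
  expect_equal(res$category[which.max(res$pseudo_F)], "CatC")
})

test_that("abundance-response correlation behaves at its fixed points", {
  ab <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5), paste0("c", 1:5))
  expect_equal(abundanceResponseCorrelation(ab, ab * 7)@r, 1, tolerance = 1e-12)
  # permutation null: correlation of shuffled statistics centers on zero
  set.seed(71)
  stat <- setNames(rexp(10), paste0("c", 1:10))
  ab10 <- setNames(runif(10), paste0("c", 1:10))
  rs <- replicate(1000, {
    shuffled <- setNames(sample(stat), names(stat))
    abundanceResponseCorrelation(ab10, shuffled)@r
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(abundanceResponseCorrelation(ab[1:2], ab[1:2]), ">= 3")
})

test_that("heatmap clustering z-scores rows and follows the hand UPGMA trace", {
  mat <- rbind(r1 = c(1, 2, 3, 4),
               r2 = c(2, 4, 6, 8),     # identical ranks as r1
               r3 = c(4, 3, 2, 1),     # exactly reversed ranks
               r4 = c(1, 3, 2, 4))     # Spearman 0.8 with r1
  hm <- heatmapCluster(mat)
  expect_equal(rowMeans(hm@matrix), c(r1 = 0, r2 = 0, r3 = 0, r4 = 0))
  expect_equal(apply(hm@matrix, 1, sd), c(r1 = 1, r2 = 1, r3 = 1, r4 = 1))
  hc <- hm@linkage
  # hand trace: {r1,r2} at 0; {r1,r2,r4} at 0.2; r3 joins at (2+2+1.8)/3
  expect_equal(hc$height, c(0, 0.2, 5.8 / 3), tolerance = 1e-12)
  expect_equal(hc$merge[1, ], c(-1, -2))
  expect_setequal(hc$merge[2, ], c(-4, 1))
  expect_setequal(hc$merge[3, ], c(-3, 2))
})

test_that("constant rows are flagged and pushed to maximal distance", {
  mat <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), k = c(5, 5, 5))
  expect_message(hm <- heatmapCluster(mat), "constant")
  expect_identical(hm@constantRows, "k")
  expect_equal(unname(hm@matrix["k", ]), c(0, 0, 0))
  # k merges last, at distance 2 from everything
  expect_equal(max(hm@linkage$height), 2)
  # z-scoring preserves ranks, so clustering is scale-invariant
  hm2 <- suppressMessages(heatmapCluster(mat * 100 + 3))
  expect_identical(hm2@linkage$merge, hm@linkage$merge)
  expect_equal(hm2@linkage$height, hm@linkage$height)
})
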