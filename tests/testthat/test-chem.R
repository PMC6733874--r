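test_that("Tanimoto similarity follows its set definition", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 1)
  suppressWarnings(expect_equal(tanimoto(c(0, 0), c(0, 0), zeroZero = "zero"), 0))
})

test_that("Tanimoto is symmetric, bounded, and 1 only for identical prints", {
  set.seed(2)
  for (i in 1:25) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    s <- tanimoto(a, b)
    expect_equal(s, tanimoto(b, a))
    expect_true(s >= 0 && s <= 1)
    if (s == 1) expect_identical(a, b)
  }
  fp <- matrix(rbinom(10 * 64, 1, 0.3), 10, 64,
               dimnames = list(letters[1:10], NULL))
  S <- tanimotoMatrix(fp)
  pairwise <- outer(1:10, 1:10, Vectorize(function(i, j) tanimoto(fp[i, ], fp[j, ])))
  expect_equal(unname(S), pairwise)
})

test_that("average-linkage clustering recovers planted structure exactly", {
  lib <- generateCompoundLibrary(14, 9, nBits = 256, seed = 5, flipRate = 0.05)
  res <- clusterHits(lib, nClusters = 14)
  expect_equal(adjustedRand(res$labels, libraryTruth(lib)$cluster), 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(res$labels, libraryTruth(lib)$cluster), 1)
  }
  # label permutation invariance under input reordering
  set.seed(3)
  perm <- sample(nrow(fingerprints(lib)))
  res2 <- clusterHits(fingerprints(lib)[perm, ], nClusters = 14)
  expect_equal(adjustedRand(res2$labels, libraryTruth(lib)$cluster[perm]), 1)
  # cutting at n gives singletons
  single <- clusterHits(fingerprints(lib)[1:9, ], nClusters = 9)
  expect_equal(length(unique(single$labels)), 9)
  expect_error(clusterHits(lib, 0), "at least 1")
})

test_that("merge heights match a brute-force average-linkage recomputation", {
  set.seed(9)
  fp <- matrix(rbinom(5 * 64, 1, 0.3), 5, 64,
               dimnames = list(paste0("c", 1:5), NULL))
  res <- clusterHits(fp, nClusters = 2)
  # brute-force: recompute average linkage from the Tanimoto distance matrix
  D <- 1 - tanimotoMatrix(fp)
  groups <- as.list(1:5)
  heights <- numeric(4)
  for (step in 1:4) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d <- mean(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights[step] <- best[1]
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  expect_equal(res$tree$height, heights)
})

test_that("enrichment factors and hypergeometric tails are exact", {
  ranked <- sprintf("c%02d", 1:10)
  ann <- data.frame(compound_id = ranked[1:3], target_id = "T")
  # all top_n annotated, background fraction 0.3 -> EF = 1/0.3
  res <- targetEnrichment(ranked, ann, topN = 3)
  expect_equal(res$EF, (3 / 3) / (3 / 10))
  # background fraction 0.1 with all of top_n annotated -> EF = 10
  ann10 <- data.frame(compound_id = ranked[1], target_id = "T")
  expect_equal(targetEnrichment(ranked, ann10, topN = 1)$EF, 10)
  # EF of the full background is exactly 1 for every target
  full <- targetEnrichment(ranked, ann, topN = 10)
  expect_equal(full$EF, 1)

  # hypergeometric p equals exhaustive enumeration over all C(10,3) draws
  draws <- combn(10, 3)
  annotated <- 1:4
  ann4 <- data.frame(compound_id = ranked[annotated], target_id = "T")
  resTop <- targetEnrichment(ranked, ann4, topN = 3)
  k <- resTop$k
  enumP <- mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
  # note ranked[1:3] are all annotated so k = 3
  expect_equal(k, 3)
  expect_equal(resTop$p_hyper, enumP)

  expect_error(targetEnrichment(ranked, data.frame(compound_id = "zz",
                                                   target_id = "TX"), 3),
               "absent from the background")
  expect_error(targetEnrichment(ranked, ann, topN = 11), "exceeds")
})

test_that("planted 5x enrichment is detected with high power", {
  set.seed(17)
  n <- 400
  ids <- sprintf("c%03d", 1:n)
  hits <- 0
  for (rep in 1:40) {
    annotated <- runif(n) < ifelse(seq_len(n) <= 60, 0.5, 0.1)  # 5x in top 60
    ann <- data.frame(compound_id = ids[annotated], target_id = "T")
    res <- targetEnrichment(ids, ann, topN = 60)
    hits <- hits + (res$p_adj < 0.05)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("permutation p-values are uniform when annotations ignore rank", {
  n <- 200
  ids <- sprintf("c%03d", 1:n)
  annIds <- ids[1:40]
  pvals <- sapply(1:1000, function(s) {
    set.seed(10000 + s)
    ranked <- sample(ids)
    targetEnrichment(ranked, data.frame(compound_id = annIds, target_id = "T"),
                     topN = 30, nPerm = 99, ties = "random",
                     seed = s)$p_perm
  })
  rate <- mean(pvals <= 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("npKi matches the printed normalization", {
  expect_equal(npKi(1), 4)
  expect_equal(npKi(0.1), 5)
  expect_equal(npKi(10), 3)
  expect_error(npKi(0), "positive")
  expect_error(npKi(-2), "positive")
  panel <- matrix(c(1, 0.1, NA, 10), 2, 2,
                  dimnames = list(c("a", "b"), c("R1", "R2")))
  np <- bindingPanel(panel)
  expect_equal(np[1, 1], 4)
  expect_true(is.na(np[1, 2]))
  expect_equal(attr(np, "unit"), "uM")
})
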