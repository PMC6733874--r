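test_that("phenoscore attains its analytic bounds and matches the Pearson oracle", {
  ref <- generateWellProfile(phenotypeClassParams("etomidate_like"), 6.25, seed = 1)
  expect_equal(phenoscore(ref, ref)$phenoscore, 1)
  expect_equal(phenoscore(-1 * ref + 5, ref)$phenoscore, -1)
  r <- phenoscore(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$phenoscore, pearsonOracle(c(1, 2, 3), c(1, 2, 4)))
  expect_false(r$degenerate)
})

test_that("phenoscore is affine invariant, symmetric, and guards degenerate input", {
  set.seed(4)
  x <- rexp(200); y <- rexp(200)
  base <- phenoscore(x, y)$phenoscore
  expect_equal(phenoscore(2.5 * x + 3, y)$phenoscore, base)
  expect_equal(phenoscore(x, 0.1 * y + 7)$phenoscore, base)
  expect_equal(phenoscore(y, x)$phenoscore, base)

  deg <- phenoscore(rep(0, 200), y)
  expect_true(deg$degenerate)
  expect_equal(deg$phenoscore, 0)
  expect_error(phenoscore(x, rep(1, 200)), "zero variance")
  expect_error(phenoscore(x, y[1:100]), "more than 1 sample")
  # off-by-one lengths are aligned by truncation
  expect_equal(phenoscore(x, c(y, 1))$phenoscore, base)
})

test_that("annealed subset selection matches exhaustive search on small instances", {
  battery <- defaultBattery()
  # 3 exact copies of a template + 3 independent noise wells: the copies win
  set.seed(10)
  template <- generateWellProfile(phenotypeClassParams("etomidate_like"), 6.25, seed = 2)
  noise <- sapply(1:3, function(s) abs(rnorm(length(template))) + 0.01)
  mi <- cbind(template, template, template, noise)
  cands <- profileSetFromColumns(mi, treatment = "etomidate", concentration = 6.25)
  dmso <- generateControlPlates(0, 4, seed = 11)
  cfg <- annealConfig(subsetSize = 3, nIterations = 3000, seed = 1)
  sel <- selectReference(cands, dmso, cfg)
  expect_setequal(memberIds(sel), c("W001", "W002", "W003"))
  oracle <- exhaustiveReference(cands, dmso, cfg)
  expect_equal(objectiveValue(sel), oracle$objective)

  # oracle equivalence across random instances with <= 8 candidates
  for (case in 1:4) {
    m <- c(5, 6, 7, 8)[case]
    cands2 <- generateControlPlates(m, 0, seed = 500 + case)
    dmso2 <- generateControlPlates(0, 5, seed = 600 + case)
    cfg2 <- annealConfig(subsetSize = 3, nIterations = 4000, seed = case)
    sel2 <- selectReference(cands2, dmso2, cfg2)
    oracle2 <- exhaustiveReference(cands2, dmso2, cfg2)
    expect_equal(objectiveValue(sel2), oracle2$objective, tolerance = 1e-12)
  }
})

test_that("annealing beats 1000 random subsets on the default-size problem", {
  fix <- referenceFixture()
  ref <- fix$reference
  X <- miMatrix(fix$candidates)
  C <- cor(X)
  dbar <- rowMeans(cor(X, miMatrix(fix$dmso)))
  set.seed(99)
  randJ <- replicate(1000, phenoscreen:::.subsetObjective(
    sample.int(ncol(X), 12), C, dbar, 1.0))
  expect_gte(objectiveValue(ref), max(randJ))
  expect_length(memberIds(ref), 12)
  # identical candidates with lambda 0: any subset is optimal with J = 1
  same <- profileSetFromColumns(matrix(rep(X[, 1], 14), ncol = 14))
  cfgl <- annealConfig(subsetSize = 4, nIterations = 200, lambdaDmso = 0, seed = 2)
  expect_equal(objectiveValue(selectReference(same, fix$dmso, cfgl)), 1)
})

test_that("simulated cutoffs recover Gaussian quantiles and are monotone", {
  gaussNull <- function(n, seed) { set.seed(seed); rnorm(n) }
  cut <- simulateCutoffs(gaussNull, nSim = 100000, seed = 1)
  expect_equal(cut$cutoff_5pct, qnorm(0.95), tolerance = 0.02)
  expect_equal(cut$cutoff_1pct, qnorm(0.99), tolerance = 0.02)
  expect_gte(cut$cutoff_1pct, cut$cutoff_5pct)
  # alpha = 1 returns the null minimum (0th quantile)
  cutAll <- simulateCutoffs(gaussNull, alphaLevels = c(1, 0.05), nSim = 5000, seed = 2)
  set.seed(2)
  expect_equal(cutAll$cutoffs[["alpha_1"]], min(rnorm(5000)))
  expect_error(simulateCutoffs(gaussNull, nSim = 10), "at least 1000")
  degNull <- function(n, seed) rep(0.5, n)
  expect_error(simulateCutoffs(degNull, nSim = 1000), "degenerate")
})

test_that("cutoff standard error shrinks at the Monte-Carlo rate", {
  cutAt <- function(n, seed) {
    simulateCutoffs(function(m, s) { set.seed(s); rnorm(m) },
                    nSim = n, seed = seed)$cutoff_5pct
  }
  se1 <- sd(sapply(1:200, function(s) cutAt(1000, s)))
  se2 <- sd(sapply(1:200, function(s) cutAt(4000, 1000 + s)))
  # quadrupling the simulation size should halve the SE, within 20%
  expect_lt(abs(se1 / se2 - 2), 0.4)
})

test_that("quality statistics follow the closed-form Z-factor and KS calibration", {
  # noiseless separation
  expect_equal(qualityStats(c(1, 1), c(0, 0))$z_factor, 1)
  # closed form on the printed-scale means/SDs: 1 - 3(0.16)/0.6 = 0.2
  set.seed(5)
  pos <- rnorm(4000, 0.7, 0.11); neg <- rnorm(4000, 0.1, 0.05)
  qs <- qualityStats(pos, neg)
  expect_equal(qs$z_factor,
               1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)))
  expect_equal(qs$z_factor, 0.2, tolerance = 0.03)
  expect_lt(qs$ks_pvalue, 1e-10)
  expect_lte(qualityStats(rnorm(50), rnorm(50))$z_factor, 1)
  # identical means: undefined, -Inf sentinel
  und <- qualityStats(c(1, 2, 3), c(3, 2, 1))
  expect_true(und$undefined)
  expect_equal(und$z_factor, -Inf)
  # same-distribution arms: KS p-values uniform over repeated seeds
  pvals <- sapply(1:200, function(s) {
    set.seed(s)
    qualityStats(rnorm(200), rnorm(200))$ks_pvalue
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("reference profiles round-trip through JSON", {
  ref <- referenceFixture()$reference
  path <- tempfile(fileext = ".json")
  writeReference(ref, path)
  back <- readReference(path)
  expect_equal(referenceSeries(back), referenceSeries(ref))
  expect_equal(memberIds(back), memberIds(ref))
  expect_equal(objectiveValue(back), objectiveValue(ref))
})
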