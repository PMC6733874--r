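# Shared fixtures, built once per test run.

# Frozen reference pipeline at default calibration: 36 positive candidates,
# 36 vehicle wells, 12-member annealed reference. Cached because several
# files score wells against the same reference.
referenceFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cands <- generateControlPlates(36, 0, seed = 401)
      dmso <- generateControlPlates(0, 36, seed = 402)
      ref <- selectReference(cands, dmso,
                             annealConfig(seed = 7, nIterations = 8000))
      cache <<- list(candidates = cands, dmso = dmso, reference = ref)
    }
    cache
  }
})

# Small ProfileSet wrapping explicit MI columns, aligned to a given battery.
profileSetFromColumns <- function(mi, train = defaultBattery(), fs = 25,
                                  treatment = "DMSO", concentration = 0) {
  mi <- as.matrix(mi)
  info <- data.frame(
    well_id = sprintf("W%03d", seq_len(ncol(mi))),
    treatment = rep_len(treatment, ncol(mi)),
    concentration_uM = rep_len(concentration, ncol(mi))
  )
  ProfileSet(mi, info, train, frameRate = fs)
}

# Direct Pearson correlation from sums of squares (independent oracle).
pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Adjusted Rand index between two labelings (contingency closed form),
# kept local so cluster-recovery checks do not depend on the clustering
# implementation under test.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nPairs <- comb2(sum(tab))
  expected <- sumI * sumJ / nPairs
  (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}
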