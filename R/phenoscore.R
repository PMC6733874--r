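#' Phenoscore: correlation of a behavioral profile with the reference
#'
#' The phenoscore is the Pearson correlation between a well's motion-index
#' series and the reference profile (equivalently `1 - d`, with `d` the
#' correlation distance), ranging from -1 (anti-correlated) to +1
#' (identical shape). It is invariant to positive affine transforms of
#' either series.
#'
#' Series of unequal length are aligned by truncation to the shorter one
#' when they differ by at most one sample (trailing-frame bookkeeping);
#' larger mismatches are an error. A zero-variance (fully immobilized) well
#' has no defined correlation: it scores 0 with `degenerate = TRUE`.
#'
#' @param x a numeric MI series, or a [ProfileSet-class].
#' @param reference a numeric series or a [ReferenceProfile-class].
#' @param ... unused.
#' @return for numeric `x`, a one-row `data.frame` with `phenoscore` and
#'   `degenerate`; for a [ProfileSet-class], one row per well with
#'   `well_id`.
#' @examples
#' phenoscore(c(1, 2, 3), c(1, 2, 4))
#' @export
#' @rdname phenoscore
setMethod("phenoscore", signature("numeric", "numeric"), function(x, reference, ...) {
  dl <- length(x) - length(reference)
  if (abs(dl) > 1L) stop("profile and reference lengths differ by more than 1 sample")
  n <- min(length(x), length(reference))
  x <- x[seq_len(n)]; reference <- reference[seq_len(n)]
  if (stats::sd(reference) == 0) stop("reference profile has zero variance")
  if (stats::sd(x) == 0) {
    return(data.frame(phenoscore = 0, degenerate = TRUE))
  }
  data.frame(phenoscore = stats::cor(x, reference), degenerate = FALSE)
})

#' @export
#' @rdname phenoscore
setMethod("phenoscore", signature("ProfileSet", "ReferenceProfile"),
  function(x, reference, ...) {
    ref <- referenceSeries(reference)
    mi <- miMatrix(x)
    res <- do.call(rbind, lapply(seq_len(ncol(mi)), function(j)
      phenoscore(mi[, j], ref)))
    cbind(data.frame(well_id = wellData(x)$well_id), res)
  })

#' @export
#' @rdname phenoscore
setMethod("phenoscore", signature("ProfileSet", "numeric"),
  function(x, reference, ...) {
    mi <- miMatrix(x)
    res <- do.call(rbind, lapply(seq_len(ncol(mi)), function(j)
      phenoscore(mi[, j], reference)))
    cbind(data.frame(well_id = wellData(x)$well_id), res)
  })

#' @rdname accessors
#' @export
setMethod("referenceSeries", "ReferenceProfile", function(x) x@profile)

#' @rdname accessors
#' @export
setMethod("memberIds", "ReferenceProfile", function(x) x@memberIds)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "ReferenceProfile", function(x) x@objectiveValue)

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile:", length(object@profile), "samples, average of",
      length(object@memberIds), "member wells; objective",
      format(object@objectiveValue, digits = 4), "\n")
})

#' Simulated-annealing configuration for reference selection
#'
#' @param subsetSize members to select (default 12, from 36 candidates).
#' @param nIterations annealing iterations.
#' @param initialTemperature starting temperature; `NULL` sets it to the SD
#'   of the objective over 100 random subsets (a scale-free default).
#' @param coolingRate geometric cooling factor per iteration (< 1).
#' @param lambdaDmso weight of the distance-to-vehicle term in the
#'   objective.
#' @param seed RNG seed for the proposal chain.
#' @return an `annealConfig` list.
#' @export
annealConfig <- function(subsetSize = 12, nIterations = 20000,
                         initialTemperature = NULL, coolingRate = 0.995,
                         lambdaDmso = 1.0, seed = 1) {
  stopifnot(subsetSize >= 1, nIterations >= 1, coolingRate > 0, coolingRate < 1)
  list(subsetSize = subsetSize, nIterations = nIterations,
       initialTemperature = initialTemperature, coolingRate = coolingRate,
       lambdaDmso = lambdaDmso, seed = seed)
}

# subset objective: mean pairwise correlation within S minus lambda times
# mean correlation of S members with the vehicle wells
.subsetObjective <- function(S, C, dbar, lambda) {
  k <- length(S)
  within <- if (k > 1) (sum(C[S, S]) - k) / (k * (k - 1)) else 1
  within - lambda * mean(dbar[S])
}

#' Select the reference profile by simulated annealing
#'
#' Searches size-`subsetSize` subsets of the candidate positive-control
#' wells for the subset maximizing
#' `J(S) = mean pairwise Pearson correlation within S
#'         - lambdaDmso * mean correlation between S and the vehicle wells`,
#' i.e. the most mutually consistent replicates that are also most distant
#' from vehicle behavior. The search uses swap-one-member proposals with
#' Metropolis acceptance and geometric cooling, tracks the best subset ever
#' visited, and is fully seeded. The returned reference is the average of
#' the selected member profiles.
#'
#' @param candidates [ProfileSet-class] of replicate positive-control wells
#'   (at least `subsetSize` of them).
#' @param dmso [ProfileSet-class] of vehicle wells (at least one).
#' @param config an [annealConfig()].
#' @return a [ReferenceProfile-class].
#' @export
selectReference <- function(candidates, dmso, config = annealConfig()) {
  X <- miMatrix(candidates)
  D <- miMatrix(dmso)
  m <- ncol(X)
  k <- config$subsetSize
  if (k > m) stop("subsetSize exceeds the number of candidate profiles")
  if (ncol(D) < 1L) stop("at least one vehicle (DMSO) profile is required")
  C <- stats::cor(X)
  dbar <- rowMeans(stats::cor(X, D))
  lambda <- config$lambdaDmso
  J <- function(S) .subsetObjective(S, C, dbar, lambda)

  set.seed(config$seed)
  T0 <- config$initialTemperature
  if (is.null(T0)) {
    Js <- replicate(100, J(sample.int(m, k)))
    T0 <- max(stats::sd(Js), 1e-6)
  }
  S <- sample.int(m, k)
  curJ <- J(S)
  bestS <- S; bestJ <- curJ
  temp <- T0
  for (it in seq_len(config$nIterations)) {
    out <- sample(S, 1L)
    pool <- setdiff(seq_len(m), S)
    if (!length(pool)) break
    inn <- pool[sample.int(length(pool), 1L)]
    Sp <- c(setdiff(S, out), inn)
    propJ <- J(Sp)
    if (propJ >= curJ || stats::runif(1) < exp((propJ - curJ) / temp)) {
      S <- Sp; curJ <- propJ
      if (curJ > bestJ) { bestS <- S; bestJ <- curJ }
    }
    temp <- temp * config$coolingRate
  }
  bestS <- sort(bestS)
  cfg <- config; cfg$initialTemperature <- T0
  new("ReferenceProfile",
      profile = rowMeans(X[, bestS, drop = FALSE]),
      memberIds = as.character(wellData(candidates)$well_id[bestS]),
      objectiveValue = bestJ,
      annealConfig = cfg,
      frameRate = frameRate(candidates))
}

#' Exhaustive reference-subset search (oracle for small problems)
#'
#' Enumerates all size-`subsetSize` subsets and returns the exact maximizer
#' of the same objective as [selectReference()]. Only feasible for small
#' candidate sets; used to validate the annealing search.
#'
#' @inheritParams selectReference
#' @return list with `members` (indices) and `objective`.
#' @export
exhaustiveReference <- function(candidates, dmso, config = annealConfig()) {
  X <- miMatrix(candidates)
  C <- stats::cor(X)
  dbar <- rowMeans(stats::cor(X, miMatrix(dmso)))
  subsets <- utils::combn(ncol(X), config$subsetSize)
  Js <- apply(subsets, 2L, .subsetObjective, C = C, dbar = dbar,
              lambda = config$lambdaDmso)
  best <- which.max(Js)
  list(members = sort(subsets[, best]), objective = Js[best])
}

#' Simulate null phenoscore cutoffs
#'
#' Draws `nSim` vehicle-class (null) wells, scores each against the frozen
#' reference, and returns upper quantiles of the null phenoscore
#' distribution: the `(1 - alpha)` quantile for each significance level.
#' By quantile monotonicity the 1% cutoff is at least the 5% cutoff.
#'
#' `nullGenerator` may return either a [ProfileSet-class]/matrix of null
#' profiles or directly a numeric vector of null phenoscores (useful for
#' calibration studies with analytically known nulls).
#'
#' @param nullGenerator `function(n, seed)` producing the null sample.
#' @param reference a [ReferenceProfile-class] (ignored when the generator
#'   returns scores directly).
#' @param alphaLevels significance levels (default 1% and 5%).
#' @param nSim null sample size (>= 1000).
#' @param seed seed passed to `nullGenerator`.
#' @return list with `cutoffs` (named per alpha), `cutoff_1pct`,
#'   `cutoff_5pct` (when those levels are requested), `nullSampleSize`, and
#'   `procedure`.
#' @export
simulateCutoffs <- function(nullGenerator, reference = NULL,
                            alphaLevels = c(0.01, 0.05), nSim = 1000, seed = 1) {
  if (nSim < 1000) stop("nSim must be at least 1000")
  nulls <- nullGenerator(nSim, seed)
  if (is.numeric(nulls) && is.null(dim(nulls))) {
    scores <- nulls
    proc <- "injected null scores"
  } else {
    sc <- phenoscore(nulls, reference)
    if (all(sc$degenerate)) stop("degenerate null: all simulated wells have zero variance")
    scores <- sc$phenoscore[!sc$degenerate]
    proc <- "vehicle-class wells scored against the frozen reference"
  }
  if (stats::sd(scores) == 0) stop("degenerate null: zero-variance score distribution")
  cuts <- stats::quantile(scores, probs = 1 - alphaLevels, names = FALSE)
  names(cuts) <- paste0("alpha_", alphaLevels)
  out <- list(cutoffs = cuts, nullSampleSize = length(scores), procedure = proc)
  if (0.01 %in% alphaLevels) out$cutoff_1pct <- cuts[[which(alphaLevels == 0.01)]]
  if (0.05 %in% alphaLevels) out$cutoff_5pct <- cuts[[which(alphaLevels == 0.05)]]
  out
}

#' Assay quality statistics for a control experiment
#'
#' Group means and sample SDs of the positive and negative control
#' phenoscores, the screening-window Z-factor
#' `1 - 3 (sd_pos + sd_neg) / |mu_pos - mu_neg|` (at most 1 by
#' construction; `-Inf` with `undefined = TRUE` when the means coincide),
#' and the two-sample Kolmogorov-Smirnov comparison of the two arms.
#'
#' @param posScores,negScores numeric phenoscore vectors (>= 2 each).
#' @return list with `mu_pos`, `sd_pos`, `mu_neg`, `sd_neg`, `z_factor`,
#'   `undefined`, `ks_statistic`, `ks_pvalue`.
#' @export
qualityStats <- function(posScores, negScores) {
  if (length(posScores) < 2L || length(negScores) < 2L) {
    stop("need at least 2 scores per arm")
  }
  mup <- mean(posScores); mun <- mean(negScores)
  sdp <- stats::sd(posScores); sdn <- stats::sd(negScores)
  if (mup == mun) {
    z <- -Inf; undef <- TRUE
  } else {
    z <- 1 - 3 * (sdp + sdn) / abs(mup - mun); undef <- FALSE
  }
  ks <- suppressWarnings(stats::ks.test(posScores, negScores))
  list(mu_pos = mup, sd_pos = sdp, mu_neg = mun, sd_neg = sdn,
       z_factor = z, undefined = undef,
       ks_statistic = unname(ks$statistic), ks_pvalue = ks$p.value)
}

#' Serialize / restore a reference profile as JSON
#'
#' @param x a [ReferenceProfile-class].
#' @param path JSON file path.
#' @return `readReference` returns a [ReferenceProfile-class].
#' @export
writeReference <- function(x, path) {
  jsonlite::write_json(
    list(profile = x@profile, memberIds = x@memberIds,
         objectiveValue = x@objectiveValue, annealConfig = x@annealConfig,
         frameRate = x@frameRate),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeReference
#' @export
readReference <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- o$annealConfig
  if (is.null(cfg$initialTemperature)) cfg["initialTemperature"] <- list(NULL)
  new("ReferenceProfile", profile = as.numeric(o$profile),
      memberIds = as.character(o$memberIds),
      objectiveValue = as.numeric(o$objectiveValue),
      annealConfig = as.list(cfg), frameRate = as.numeric(o$frameRate))
}
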