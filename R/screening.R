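#' Reference statistics of vehicle wells for the immobilization index
#'
#' @param dmso a [ProfileSet-class] of vehicle wells.
#' @param tailS post-stimulus tail for response windows (s).
#' @return list with `median_violet_mag`.
#' @export
dmsoReferenceStats <- function(dmso, tailS = 1) {
  mags <- responseMagnitudes(dmso, tailS = tailS)
  if (all(is.na(mags$violet_mag))) stop("vehicle wells have no violet events")
  med <- stats::median(mags$violet_mag, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) stop("vehicle violet-response magnitude must be positive")
  list(median_violet_mag = med)
}

#' Immobilization index of a well
#'
#' Degree of suppression of the light-evoked response relative to vehicle:
#' `1 - clip(violet_mag / median violet_mag of DMSO wells, 0, 1)`. 0 means
#' vehicle-like light response, 1 fully immobilized. (The light assay is the
#' screen's motor-activity readout, so immobilization is defined from it.)
#'
#' @param x a [ProfileSet-class] or numeric MI series.
#' @param dmsoStats result of [dmsoReferenceStats()].
#' @param train,fs battery and sampling rate for numeric input.
#' @param tailS post-stimulus tail (s).
#' @param ... unused.
#' @return numeric vector in `[0, 1]` (one value per well).
#' @export
#' @rdname immobilizationIndex
setMethod("immobilizationIndex", signature("ProfileSet", "list"),
  function(x, dmsoStats, tailS = 1, ...) {
    mags <- responseMagnitudes(x, tailS = tailS)
    if (all(is.na(mags$violet_mag))) stop("profiles have no violet events")
    1 - pmin(pmax(mags$violet_mag / dmsoStats$median_violet_mag, 0), 1)
  })

#' @export
#' @rdname immobilizationIndex
setMethod("immobilizationIndex", signature("numeric", "list"),
  function(x, dmsoStats, train, fs = 25, tailS = 1, ...) {
    mags <- responseMagnitudes(x, train = train, fs = fs, tailS = tailS)
    if (is.na(mags$violet_mag)) stop("profile has no violet events")
    1 - min(max(mags$violet_mag / dmsoStats$median_violet_mag, 0), 1)
  })

#' Build a per-well screen table from profiles and a reference
#'
#' Scores every well (phenoscore, immobilization index, total MI) and tags
#' vehicle wells as controls. The vehicle wells inside `profiles`
#' (treatment `"DMSO"`) provide the immobilization reference.
#'
#' @param profiles a [ProfileSet-class] including DMSO control wells.
#' @param reference a [ReferenceProfile-class].
#' @param tailS post-stimulus tail (s).
#' @return `data.frame` with columns `compound_id`, `well_id`,
#'   `phenoscore`, `degenerate`, `immobilization_index`, `total_mi`,
#'   `concentration_uM`, `is_control`.
#' @export
screenTable <- function(profiles, reference, tailS = 1) {
  cd <- as.data.frame(wellData(profiles))
  isCtl <- cd$treatment == "DMSO"
  if (!any(isCtl)) stop("profiles must include DMSO control wells")
  stats0 <- dmsoReferenceStats(profiles[, isCtl], tailS = tailS)
  sc <- phenoscore(profiles, reference)
  data.frame(
    compound_id = cd$treatment,
    well_id = cd$well_id,
    phenoscore = sc$phenoscore,
    degenerate = sc$degenerate,
    immobilization_index = immobilizationIndex(profiles, stats0, tailS = tailS),
    total_mi = colSums(miMatrix(profiles)),
    concentration_uM = cd$concentration_uM,
    is_control = isCtl
  )
}

#' Rank compounds and call hits, toxics and inactives
#'
#' Aggregates wells to one score per compound (mean phenoscore over
#' replicate wells at the screening concentration), ranks compounds by
#' score (descending, ties broken by lexicographic compound id so the
#' top-k rule is deterministic), and calls the top `kHits` compounds hits.
#' Among the remaining compounds, those with mean immobilization index at
#' or above `toxicThreshold` (default 0.9) and phenoscore below the hit
#' floor (the lowest phenoscore among called hits) are called toxic; the
#' rest are inactive. Vehicle wells are passed through with call
#' `"control"`. Every compound receives exactly one call.
#'
#' @param table a [screenTable()] `data.frame`.
#' @param kHits number of hits to call (default 125).
#' @param toxicThreshold immobilization-index threshold for toxic calls.
#' @return the input table with a `call` column; the per-compound summary
#'   (one row per compound: mean scores, rank, call) is attached as
#'   `attr(x, "compounds")`.
#' @export
rankAndCall <- function(table, kHits = 125, toxicThreshold = 0.9) {
  if (kHits <= 0) stop("kHits must be positive")
  cmp <- table[!table$is_control, , drop = FALSE]
  agg <- stats::aggregate(
    cbind(phenoscore, immobilization_index) ~ compound_id, data = cmp, FUN = mean)
  if (kHits > nrow(agg)) stop("kHits exceeds the number of compounds")
  ord <- order(-agg$phenoscore, agg$compound_id)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg$call <- "inactive"
  agg$call[seq_len(kHits)] <- "hit"
  hitFloor <- min(agg$phenoscore[seq_len(kHits)])
  toxic <- agg$call != "hit" &
    agg$immobilization_index >= toxicThreshold & agg$phenoscore < hitFloor
  agg$call[toxic] <- "toxic"
  rownames(agg) <- NULL
  table$call <- ifelse(table$is_control, "control",
                       agg$call[match(table$compound_id, agg$compound_id)])
  attr(table, "compounds") <- agg
  table
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on log10 concentration,
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) - log10(c))))`,
#' with multi-start initialization (EC50 started at every tested
#' concentration, Hill slopes 0.5/1/2/4, both signs) via
#' [minpack.lm::nlsLM]. EC50 is constrained to within a factor of 10 of the
#' tested concentration span and reported on the linear uM scale.
#' Non-convergence (including flat responses with no resolvable slope) is
#' reported as `converged = FALSE` with diagnostics, never as an exception.
#'
#' @param concentration tested concentrations (uM; >= 4 distinct values).
#' @param response per-well phenoscores or magnitudes, same length.
#' @return list with `ec50_uM`, `hill`, `top`, `bottom`, `rmse`,
#'   `converged`, and `message`.
#' @export
fitDoseResponse <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  lc <- log10(concentration)
  span <- range(lc)
  ylo <- min(response); yhi <- max(response)
  if (yhi - ylo < .Machine$double.eps^0.5) {
    return(list(ec50_uM = NA_real_, hill = NA_real_, top = mean(response),
                bottom = mean(response), rmse = stats::sd(response),
                converged = FALSE, message = "flat response"))
  }
  f <- function(lc, bottom, top, lec50, hill) {
    bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc)))
  }
  dat <- data.frame(lc = lc, y = response)
  best <- NULL
  scale2 <- (yhi - ylo)^2 * length(response)
  starts <- expand.grid(lec50 = stats::quantile(lc, c(0.1, 0.5, 0.9), names = FALSE),
                        hill = c(0.5, 1, 2, 4, -1, -2))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f(lc, bottom, top, lec50, hill), data = dat,
        start = list(bottom = ylo, top = yhi,
                     lec50 = starts$lec50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, top = -Inf, lec50 = span[1] - 1, hill = -20),
        upper = c(bottom = Inf, top = Inf, lec50 = span[2] + 1, hill = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    if (best$rss < 1e-12 * scale2) break   # essentially exact fit
  }
  if (is.null(best)) {
    return(list(ec50_uM = NA_real_, hill = NA_real_, top = NA_real_,
                bottom = NA_real_, rmse = NA_real_, converged = FALSE,
                message = "no start converged"))
  }
  p <- stats::coef(best$fit)
  list(ec50_uM = 10^unname(p["lec50"]), hill = unname(p["hill"]),
       top = unname(p["top"]), bottom = unname(p["bottom"]),
       rmse = sqrt(best$rss / length(response)), converged = TRUE,
       message = "ok")
}

#' Efficacy window over a concentration ladder
#'
#' Marks each tested concentration strong when its mean phenoscore reaches
#' `strongCutoff` (typically the simulated 5% cutoff), then reports the
#' longest contiguous run of strong concentrations (the first such run on
#' ties). Bell-shaped compounds lose the top of the ladder and show a
#' bounded window.
#'
#' @param doseTable `data.frame` with `concentration_uM` and `phenoscore`
#'   (replicate rows allowed).
#' @param strongCutoff phenoscore threshold for a strong phenocopy.
#' @return list with `perConcentration` (`data.frame`: concentration, mean
#'   phenoscore, strength) and `window` (concentrations in the maximal
#'   strong run; empty when all weak).
#' @export
efficacyWindow <- function(doseTable, strongCutoff) {
  if (!nrow(doseTable)) stop("empty dose table")
  agg <- stats::aggregate(phenoscore ~ concentration_uM, data = doseTable, FUN = mean)
  agg <- agg[order(agg$concentration_uM), , drop = FALSE]
  agg$strength <- ifelse(agg$phenoscore >= strongCutoff, "strong", "weak")
  r <- rle(agg$strength == "strong")
  window <- numeric(0)
  if (any(r$values)) {
    lens <- ifelse(r$values, r$lengths, 0L)
    b <- which.max(lens)   # first maximal run on ties
    start <- sum(r$lengths[seq_len(b - 1L)]) + 1L
    window <- agg$concentration_uM[start:(start + r$lengths[b] - 1L)]
  }
  list(perConcentration = agg, window = window)
}

#' Reproducibility rate of primary hits on retest
#'
#' Fraction of primary hit compounds whose dose-response retest reaches the
#' strong-phenoscore criterion at one or more concentrations.
#'
#' @param primaryHits character vector of primary hit compound ids.
#' @param retest `data.frame` with `compound_id`, `concentration_uM`,
#'   `phenoscore` (per-concentration summaries or per-well rows).
#' @param criterion strong-phenoscore threshold.
#' @return fraction in `[0, 1]`.
#' @export
reproducibilityRate <- function(primaryHits, retest, criterion) {
  missing <- setdiff(primaryHits, retest$compound_id)
  if (length(missing)) {
    stop("missing retests for: ", paste(missing, collapse = ", "))
  }
  passed <- vapply(primaryHits, function(id) {
    any(retest$phenoscore[retest$compound_id == id] >= criterion)
  }, logical(1))
  mean(passed)
}
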