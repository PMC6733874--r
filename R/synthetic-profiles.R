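# Battery signal templates: one unit-amplitude column per event, so per-event
# amplitude jitter is a matrix-vector product. Computed once per battery.
.batteryTemplates <- function(train, cfg) {
  fs <- cfg$frameRate
  n <- round(train@totalDuration * fs)
  t <- seq_len(n) / fs
  ev <- stimulusEvents(train)
  grp <- .typeGroup(ev$type)
  alphaKernel <- function(onset, tau, supportS) {
    tau_rel <- t - onset
    k <- numeric(n)
    in_sup <- tau_rel >= 0 & tau_rel <= supportS
    k[in_sup] <- (tau_rel[in_sup] / tau) * exp(1 - tau_rel[in_sup] / tau)
    k
  }
  acIdx <- which(grp == "acoustic")
  viIdx <- which(grp == "violet")
  Aac <- if (length(acIdx)) {
    vapply(acIdx, function(r)
      ev$amplitude[r] * alphaKernel(ev$onset_s[r], cfg$acousticTau, cfg$acousticSupportS),
      numeric(n))
  } else matrix(0, n, 0)
  Avi <- if (length(viIdx)) {
    vapply(viIdx, function(r) {
      box <- as.numeric(t >= ev$onset_s[r] & t < ev$onset_s[r] + ev$duration_s[r])
      ev$amplitude[r] * (box + cfg$violetTransientAmp *
                           alphaKernel(ev$onset_s[r], cfg$violetTau, 2))
    }, numeric(n))
  } else matrix(0, n, 0)
  list(n = n, t = t, Aac = Aac, Avi = Avi)
}

.smoothNoise <- function(n, widthSamples, sd) {
  x <- stats::rnorm(n + 2 * widthSamples)
  sm <- stats::filter(x, rep(1 / widthSamples, widthSamples), sides = 2)
  sm <- sm[(widthSamples + 1):(widthSamples + n)]
  sm <- sm / stats::sd(sm)
  sm * sd
}

# One well's MI series. RNG state must already be set by the caller.
.simulateWell <- function(params, effectF, tmpl, cfg, nFish = 8, noiseFree = FALSE) {
  interp <- function(gain) 1 + (gain - 1) * effectF
  if (noiseFree) {
    wellMult <- 1; jG <- c(1, 1, 1)
    evA <- rep(1, ncol(tmpl$Aac)); evV <- rep(1, ncol(tmpl$Avi))
    base <- rep(1, tmpl$n)
    noise <- 0
  } else {
    wellMult <- exp(stats::rnorm(1, 0, params$wellNoiseSd))
    jG <- exp(stats::rnorm(3, 0, params$gainJitterSd))
    evA <- exp(stats::rnorm(ncol(tmpl$Aac), 0, cfg$eventJitterSd))
    evV <- exp(stats::rnorm(ncol(tmpl$Avi), 0, cfg$eventJitterSd))
    base <- pmax(1 + .smoothNoise(tmpl$n, round(cfg$baselineSmoothS * cfg$frameRate),
                                  cfg$baselineNoiseSd), 0)
    dmsoNoise <- cfg$classes$dmso$measurementNoiseSd
    sdN <- ((1 - effectF) * dmsoNoise + effectF * params$measurementNoiseSd) *
      exp(stats::rnorm(1, 0, params$noiseJitterSd)) * sqrt(8 / nFish)
    noise <- stats::rnorm(tmpl$n, 0, sdN)
  }
  gB <- interp(params$baselineGain) * jG[1]
  gA <- interp(params$acousticGain) * jG[2]
  gV <- interp(params$violetGain) * jG[3]
  sig <- gB * cfg$baselineLevel * base +
    gA * cfg$acousticAmp * as.vector(tmpl$Aac %*% evA) +
    gV * cfg$violetAmp * as.vector(tmpl$Avi %*% evV)
  pmax(wellMult * sig + noise, 0)
}

#' Simulate one well's behavioral profile
#'
#' Draws a single motion-index series from the generative model described in
#' [generatorDefaults()]: class-specific gains (interpolated from vehicle to
#' the class value by the compound's dose law), an alpha-function startle
#' kernel per acoustic tap, a sustained boxcar per light pulse, smoothed
#' baseline activity, a lognormal per-well multiplier and additive
#' measurement noise, truncated at zero. Fully seeded and reproducible.
#'
#' @param classParams a [phenotypeClassParams()] list.
#' @param concentration treatment concentration (uM, >= 0).
#' @param seed integer seed for this well.
#' @param law a [doseLaw()] mapping concentration to effect fraction;
#'   default is the reference law (`ec50` 1 uM, Hill slope 2).
#' @param battery a [StimulusTrain-class]; default [defaultBattery()].
#' @param nFish fish per well (noise variance scales as `8 / nFish`).
#' @param noiseFree if `TRUE`, return the deterministic mean trace (used by
#'   dose-response construction checks).
#' @param cfg generator constants, default [generatorDefaults()].
#' @return numeric MI series (length `totalDuration * frameRate`).
#' @export
generateWellProfile <- function(classParams, concentration = 0, seed = 1,
                                law = generatorDefaults()$referenceDoseLaw,
                                battery = defaultBattery(), nFish = 8,
                                noiseFree = FALSE, cfg = generatorDefaults()) {
  if (concentration < 0) stop("concentration must be non-negative")
  tmpl <- .batteryTemplates(battery, cfg)
  # vehicle is the dose-law origin; the toxic phenotype is modelled as
  # concentration-independent immobilization
  f <- if (classParams$name %in% c("dmso", "toxic")) 1 else doseFactor(law, concentration)
  set.seed(seed)
  .simulateWell(classParams, f, tmpl, cfg, nFish = nFish, noiseFree = noiseFree)
}

# shared worker: builds a ProfileSet from a per-well spec data.frame with
# columns class, concentration, treatment, well_id, plate_id, substream
.generateProfiles <- function(spec, rootSeed, battery, cfg, nFish = 8,
                              laws = NULL, noiseFree = FALSE) {
  tmpl <- .batteryTemplates(battery, cfg)
  classes <- lapply(stats::setNames(nm = unique(spec$class)), function(nm)
    c(list(name = nm), cfg$classes[[nm]]))
  mi <- matrix(0, tmpl$n, nrow(spec))
  for (i in seq_len(nrow(spec))) {
    p <- classes[[spec$class[i]]]
    law <- if (!is.null(laws)) laws[[spec$treatment[i]]] else cfg$referenceDoseLaw
    f <- if (p$name %in% c("dmso", "toxic")) 1 else doseFactor(law, spec$concentration[i])
    set.seed(.substreamSeed(rootSeed, spec$substream[i]))
    mi[, i] <- .simulateWell(p, f, tmpl, cfg, nFish = nFish, noiseFree = noiseFree)
  }
  info <- data.frame(
    well_id = spec$well_id, plate_id = spec$plate_id,
    treatment = spec$treatment, concentration_uM = spec$concentration,
    n_fish = nFish, class = spec$class
  )
  ProfileSet(mi, info, battery, frameRate = cfg$frameRate)
}

#' Simulate control plates (positive and negative wells)
#'
#' Positives are drawn from the `etomidate_like` class at the reference
#' concentration (6.25 uM); negatives from the `dmso` class. Under the
#' default calibration the full pipeline (reference selection then scoring)
#' reproduces the control phenoscore statistics of a well-separated screen.
#' Each well has its own deterministic RNG substream, so changing `nPos`
#' never perturbs the negative wells and vice versa.
#'
#' @param nPos,nNeg numbers of positive / negative wells (>= 0).
#' @param seed root seed.
#' @param battery a [StimulusTrain-class].
#' @param cfg generator constants.
#' @return a [ProfileSet-class]; `wellData(x)$class` records ground truth.
#' @export
generateControlPlates <- function(nPos, nNeg, seed = 1,
                                  battery = defaultBattery(),
                                  cfg = generatorDefaults()) {
  stopifnot(nPos >= 0, nNeg >= 0)
  spec <- rbind(
    if (nPos > 0) data.frame(
      class = "etomidate_like", concentration = cfg$referenceConc,
      treatment = "etomidate", well_id = sprintf("POS%04d", seq_len(nPos)),
      plate_id = sprintf("P%02d", (seq_len(nPos) - 1) %/% 96 + 1),
      substream = seq_len(nPos)),
    if (nNeg > 0) data.frame(
      class = "dmso", concentration = 0, treatment = "DMSO",
      well_id = sprintf("NEG%04d", seq_len(nNeg)),
      plate_id = sprintf("P%02d", (seq_len(nNeg) - 1) %/% 96 + 1),
      substream = 1000000 + seq_len(nNeg))
  )
  .generateProfiles(spec, seed, battery, cfg)
}

#' Simulate a primary screen with planted hits and toxics
#'
#' Assigns each compound a phenotype class (exact counts
#' `round(n * fraction)` of `etomidate_like` hits and `toxic` compounds; the
#' remainder inactive), simulates one well per compound at the screening
#' concentration (default 10 uM), adds DMSO control wells, and builds a
#' matching [CompoundLibrary-class] whose truth table records every
#' compound's class and dose law. Hit compounds receive per-compound EC50s
#' lognormally scattered around 1 uM and clustered fingerprints; inactive
#' and toxic compounds receive random fingerprints.
#'
#' @param nCompounds library size.
#' @param hitFraction,toxicFraction class fractions in `[0, 1]`, sum <= 1.
#' @param seed root seed.
#' @param nControls DMSO control wells (default `round(0.25 * nCompounds)`,
#'   mirroring the roughly 1:4 control:compound ratio of a production
#'   screen).
#' @param cfg generator constants.
#' @param battery a [StimulusTrain-class].
#' @return list with elements `profiles` ([ProfileSet-class]) and
#'   `library` ([CompoundLibrary-class]).
#' @export
generateScreen <- function(nCompounds, hitFraction = 0.1, toxicFraction = 0.05,
                           seed = 1, nControls = round(0.25 * nCompounds),
                           cfg = generatorDefaults(), battery = defaultBattery()) {
  if (hitFraction < 0 || toxicFraction < 0 || hitFraction + toxicFraction > 1) {
    stop("fractions must be in [0,1] and sum to at most 1")
  }
  nHit <- round(nCompounds * hitFraction)
  nTox <- round(nCompounds * toxicFraction)
  ids <- sprintf("CMP%05d", seq_len(nCompounds))
  set.seed(.substreamSeed(seed, 2000000))
  ord <- sample.int(nCompounds)
  class <- rep("inactive", nCompounds)
  class[ord[seq_len(nHit)]] <- "etomidate_like"
  if (nTox > 0) class[ord[nHit + seq_len(nTox)]] <- "toxic"
  ec50 <- ifelse(class == "etomidate_like", exp(stats::rnorm(nCompounds, 0, 0.4)), NA)
  laws <- lapply(seq_len(nCompounds), function(i) {
    if (class[i] == "etomidate_like") doseLaw(ec50[i], 2) else doseLaw(1, 2)
  })
  names(laws) <- ids
  spec <- rbind(
    data.frame(class = class, concentration = cfg$screeningConc, treatment = ids,
               well_id = ids, plate_id = sprintf("S%02d", (seq_len(nCompounds) - 1) %/% 96 + 1),
               substream = seq_len(nCompounds)),
    if (nControls > 0) data.frame(
      class = "dmso", concentration = 0, treatment = "DMSO",
      well_id = sprintf("CTL%04d", seq_len(nControls)),
      plate_id = "S00", substream = 1000000 + seq_len(nControls))
  )
  profiles <- .generateProfiles(spec, seed, battery, cfg, laws = laws)

  # fingerprints: hits share planted structural clusters; others are random
  nBits <- 256L
  fp <- matrix(stats::rbinom(nCompounds * nBits, 1L, 0.15), nCompounds, nBits,
               dimnames = list(ids, NULL))
  hitIdx <- which(class == "etomidate_like")
  cluster <- rep(NA_integer_, nCompounds)
  if (length(hitIdx)) {
    nClus <- max(1L, ceiling(length(hitIdx) / 9))
    cluster[hitIdx] <- rep(seq_len(nClus), length.out = length(hitIdx))
    for (cl in seq_len(nClus)) {
      seedFp <- stats::rbinom(nBits, 1L, 0.15)
      for (i in hitIdx[cluster[hitIdx] == cl]) {
        flip <- stats::runif(nBits) < 0.05
        fp[i, ] <- ifelse(flip, 1L - seedFp, seedFp)
      }
    }
  }
  ann <- data.frame(
    compound_id = ids,
    annotated = stats::runif(nCompounds) < ifelse(class == "etomidate_like", 0.6, 0.05)
  )
  ann <- data.frame(compound_id = ann$compound_id[ann$annotated],
                    target_id = "T_planted")
  truth <- data.frame(compound_id = ids, class = class, ec50_uM = ec50,
                      hill = ifelse(class == "etomidate_like", 2, NA),
                      cluster = cluster)
  lib <- new("CompoundLibrary", fingerprints = fp, annotations = ann, truth = truth)
  list(profiles = profiles, library = lib)
}

#' Simulate a dose-response series for one compound
#'
#' @param classParams a [phenotypeClassParams()] list (the compound's
#'   phenotype at saturating concentration).
#' @param law the compound's [doseLaw()].
#' @param concentrations tested ladder (uM, > 0); default 7 half-log steps
#'   0.1--100 uM.
#' @param replicates wells per concentration (default 12).
#' @param seed root seed.
#' @param noiseFree if `TRUE`, deterministic mean traces.
#' @param battery,cfg as elsewhere.
#' @return a [ProfileSet-class] with `replicates * length(concentrations)`
#'   wells.
#' @export
generateDoseSeries <- function(classParams, law,
                               concentrations = 10^seq(-1, 2, by = 0.5),
                               replicates = 12, seed = 1, noiseFree = FALSE,
                               battery = defaultBattery(),
                               cfg = generatorDefaults()) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  grid <- expand.grid(rep = seq_len(replicates), conc = concentrations)
  spec <- data.frame(
    class = classParams$name, concentration = grid$conc, treatment = "compound",
    well_id = sprintf("D%03d_R%02d", match(grid$conc, concentrations), grid$rep),
    plate_id = "DR1", substream = seq_len(nrow(grid))
  )
  laws <- list(compound = law)
  .generateProfiles(spec, seed, battery, cfg, laws = laws, noiseFree = noiseFree)
}

#' Simulate a small blob-based video frame stack
#'
#' Produces a grayscale stack (time x height x width) of Gaussian blobs
#' doing a random walk on a dark background -- just enough image structure
#' to exercise [computeMotionIndex()]; this is not a rendering of larval
#' swimming.
#'
#' @param nFrames number of frames (>= 2).
#' @param dims `c(height, width)` in pixels.
#' @param nBlobs number of moving blobs.
#' @param seed integer seed.
#' @return non-negative 3-D array.
#' @export
generateFrameStack <- function(nFrames = 10, dims = c(16, 16), nBlobs = 3, seed = 1) {
  stopifnot(nFrames >= 2)
  set.seed(seed)
  h <- dims[1]; w <- dims[2]
  pos <- cbind(stats::runif(nBlobs, 1, h), stats::runif(nBlobs, 1, w))
  out <- array(0, c(nFrames, h, w))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (f in seq_len(nFrames)) {
    frame <- matrix(0, h, w)
    for (b in seq_len(nBlobs)) {
      frame <- frame + 100 * exp(-((yy - pos[b, 1])^2 + (xx - pos[b, 2])^2) / 4)
    }
    out[f, , ] <- frame + matrix(abs(stats::rnorm(h * w, 0, 1)), h, w)
    pos <- pos + matrix(stats::rnorm(nBlobs * 2, 0, 1.5), nBlobs, 2)
    pos[, 1] <- pmin(pmax(pos[, 1], 1), h)
    pos[, 2] <- pmin(pmax(pos[, 2], 1), w)
  }
  out
}
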