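#' Hill dose law (optionally bell-shaped)
#'
#' Parameterizes the concentration dependence of a compound's behavioral
#' effect. The ascending arm is a Hill function with midpoint `ec50` (uM)
#' and slope `hill`; an optional descending arm (`ec50Hi`, `hillHi`) models
#' compounds whose phenotype collapses at high concentration (e.g. frank
#' toxicity above the sedative window), producing a bell-shaped response and
#' hence a bounded efficacy window.
#'
#' @param ec50 ascending-arm midpoint, uM (> 0).
#' @param hill ascending Hill slope (> 0).
#' @param top,bottom asymptotes of the effect fraction (defaults 1, 0).
#' @param ec50Hi,hillHi optional descending arm; `ec50Hi` must exceed `ec50`.
#' @return a `doseLaw` list.
#' @examples
#' doseFactor(doseLaw(1, 2), c(0.1, 1, 10))
#' @export
doseLaw <- function(ec50, hill, top = 1, bottom = 0, ec50Hi = NULL, hillHi = NULL) {
  if (ec50 <= 0 || hill <= 0) stop("ec50 and hill must be positive")
  if (!is.null(ec50Hi) && ec50Hi <= ec50) stop("ec50Hi must exceed ec50")
  structure(list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
                 ec50Hi = ec50Hi, hillHi = hillHi), class = "doseLaw")
}

#' @rdname doseLaw
#' @param law a `doseLaw`.
#' @param conc concentrations (uM, >= 0).
#' @return `doseFactor`: effect fraction in `[bottom, top]` at each
#'   concentration.
#' @export
doseFactor <- function(law, conc) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  up <- ifelse(conc == 0, 0, conc^law$hill / (conc^law$hill + law$ec50^law$hill))
  eff <- up
  if (!is.null(law$ec50Hi)) {
    down <- ifelse(conc == 0, 0,
                   conc^law$hillHi / (conc^law$hillHi + law$ec50Hi^law$hillHi))
    eff <- up * (1 - down)
  }
  law$bottom + (law$top - law$bottom) * eff
}

#' Generator defaults: the documented calibration of the synthetic screen
#'
#' All constants of the synthetic behavioral model live here, in one place,
#' so the calibration that makes the default control plates reproduce the
#' screen's printed control phenoscore statistics (positive wells 0.71 with
#' SD 0.11; DMSO wells 0.2 with SD 0.05) is explicit and versioned. Units:
#' seconds for times, arbitrary motion-index units for amplitudes.
#'
#' The well model is
#' `MI(t) = m_w * [gB * b(t) + gA * sum_taps K_ac + gV * sum_pulses K_vi] + eps(t)`,
#' truncated at zero, where `b(t)` is smoothed positive baseline noise,
#' `K_ac` an alpha-function startle kernel (~0.5 s decay), `K_vi` a
#' sustained boxcar with an onset transient, `m_w` a lognormal well effect,
#' and the class gains interpolate from the vehicle value (1) to the class
#' value according to the compound's [doseLaw()]. Per-class lognormal
#' jitters on gains and on the measurement-noise level create the
#' well-to-well phenoscore spread observed on real control plates.
#'
#' @return named list of generator constants; see source for every field.
#' @export
generatorDefaults <- function() {
  list(
    frameRate = 25,
    baselineLevel = 0.5,
    baselineNoiseSd = 0.25,
    baselineSmoothS = 1,
    acousticAmp = 1.0,
    acousticTau = 0.12,
    acousticSupportS = 1.5,
    violetAmp = 1.0,
    violetTransientAmp = 1.0,
    violetTau = 0.3,
    eventJitterSd = 0.25,
    referenceConc = 6.25,
    referenceDoseLaw = doseLaw(1, 2),
    screeningConc = 10,
    classes = list(
      dmso = list(baselineGain = 1, acousticGain = 1, violetGain = 1,
                  wellNoiseSd = 0.15, measurementNoiseSd = 0.42,
                  gainJitterSd = 0.25, noiseJitterSd = 0.18),
      etomidate_like = list(baselineGain = 0.3, acousticGain = 4, violetGain = 0.17,
                            wellNoiseSd = 0.15, measurementNoiseSd = 0.47,
                            gainJitterSd = 0.20, noiseJitterSd = 0.26),
      toxic = list(baselineGain = 0.002, acousticGain = 0.002, violetGain = 0.002,
                   wellNoiseSd = 0.15, measurementNoiseSd = 0.002,
                   gainJitterSd = 0.10, noiseJitterSd = 0.10),
      stimulant = list(baselineGain = 2, acousticGain = 1.5, violetGain = 1.3,
                       wellNoiseSd = 0.15, measurementNoiseSd = 0.42,
                       gainJitterSd = 0.25, noiseJitterSd = 0.18),
      inactive = list(baselineGain = 1, acousticGain = 1, violetGain = 1,
                      wellNoiseSd = 0.15, measurementNoiseSd = 0.42,
                      gainJitterSd = 0.25, noiseJitterSd = 0.18)
    )
  )
}

#' Phenotype class parameters
#'
#' Looks up the generative parameters of one phenotype class from the
#' default calibration (see [generatorDefaults()]), optionally overriding
#' fields. Vehicle (`dmso`) has unit gains; `etomidate_like` combines
#' sedation (low baseline, suppressed light response) with an amplified
#' acoustic startle; `toxic` has all gains near zero (immobilized).
#'
#' @param name one of `dmso`, `etomidate_like`, `toxic`, `stimulant`,
#'   `inactive`.
#' @param ... named overrides of individual fields.
#' @return list of class parameters with a `name` field.
#' @export
phenotypeClassParams <- function(name = c("dmso", "etomidate_like", "toxic",
                                          "stimulant", "inactive"), ...) {
  name <- match.arg(name)
  p <- generatorDefaults()$classes[[name]]
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  if (any(unlist(p[c("baselineGain", "acousticGain", "violetGain")]) < 0)) {
    stop("gains must be non-negative")
  }
  c(list(name = name), p)
}

# deterministic per-well substream seed: adding wells never perturbs others
.substreamSeed <- function(rootSeed, index) {
  s <- ((as.numeric(rootSeed) %% 2147483647) * 48271 + index * 8191 + 1) %% 2147483647
  as.integer(s)
}
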