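#' Motion index from a video frame stack
#'
#' The motion index (MI) at step `t` is the sum over pixels of absolute
#' intensity differences between consecutive frames,
#' `MI[t] = sum(|frame[t+1] - frame[t]|)`, giving a series one shorter than
#' the stack. MI sample `t` carries the timestamp of frame `t + 1`.
#'
#' @param stack 3-D non-negative intensity array, time x height x width.
#' @return numeric motion-index series of length `dim(stack)[1] - 1`.
#' @examples
#' st <- generateFrameStack(nFrames = 10, dims = c(8, 8), seed = 1)
#' mi <- computeMotionIndex(st)
#' @export
computeMotionIndex <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be a 3-D array (time x height x width)")
  }
  nt <- dim(stack)[1L]
  if (nt < 2L) stop("a frame stack needs at least 2 frames")
  if (any(stack < 0)) stop("frame intensities must be non-negative")
  flat <- matrix(stack, nrow = nt)   # frames as rows, pixels as columns
  rowSums(abs(flat[-1L, , drop = FALSE] - flat[-nt, , drop = FALSE]))
}

#' Normalize a motion-index series
#'
#' Applies `nMI = (MI - min(MI)) / max(MI)`. Note the divisor is the series
#' maximum (not `max - min`), so the normalized maximum is
#' `(max - min)/max`, which is below 1 whenever the minimum is positive.
#'
#' A fully immobilized well yields an all-zero MI with no admissible divisor;
#' by default this is an error, but pipeline callers can set
#' `degenerateOK = TRUE` to obtain an all-zero nMI carrying a
#' `degenerate` attribute instead.
#'
#' @param mi non-negative motion-index series.
#' @param degenerateOK if `TRUE`, all-zero input returns all zeros flagged
#'   with `attr(, "degenerate") = TRUE` instead of erroring.
#' @return normalized series (with a `degenerate` attribute when flagged).
#' @examples
#' normalizeMotionIndex(c(0, 5, 10))  # 0, 0.5, 1
#' @export
normalizeMotionIndex <- function(mi, degenerateOK = FALSE) {
  if (any(mi < 0)) stop("motion index must be non-negative")
  mx <- max(mi)
  if (mx <= 0) {
    if (!degenerateOK) stop("degenerate profile: all-zero motion index")
    out <- numeric(length(mi))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (mi - min(mi)) / mx
  attr(out, "degenerate") <- FALSE
  out
}

#' Startle magnitude: trapezoidal integral of MI over a stimulus window
#'
#' Numerically integrates the motion index over a stimulus window using the
#' trapezoidal rule at the series' sampling spacing. With no window given,
#' the whole series is integrated.
#'
#' @param mi motion-index series.
#' @param fs sampling rate (Hz); `fs = 1` gives unit spacing.
#' @param onsetS,durationS optional event window (s); half-open
#'   `[onset, onset + duration + tail)`.
#' @param tailS post-stimulus tail to include (s, default 0).
#' @return non-negative scalar.
#' @examples
#' startleMagnitude(c(0, 1, 0))           # 1: triangle area
#' startleMagnitude(rep(2, 5))            # 8: c * (n - 1)
#' @export
startleMagnitude <- function(mi, fs = 1, onsetS = NULL, durationS = NULL,
                             tailS = 0) {
  if (is.null(onsetS)) {
    idx <- seq_along(mi)
  } else {
    idx <- eventWindow(length(mi), fs, onsetS, durationS, tailS)
  }
  if (length(idx) < 2L) stop("invalid window: fewer than 2 samples overlap the profile")
  pracma::trapz(idx / fs, mi[idx])
}

.typeGroup <- function(type) {
  ifelse(grepl("^acoustic", type), "acoustic", as.character(type))
}

.magnitudesOne <- function(mi, train, fs, tailS) {
  ev <- stimulusEvents(train)
  grp <- .typeGroup(ev$type)
  out <- list(acoustic_mag = NA_real_, violet_mag = NA_real_)
  for (g in c("acoustic", "violet")) {
    rows <- which(grp == g)
    if (!length(rows)) next   # absent type stays NA, not zero
    maxima <- vapply(rows, function(r) {
      idx <- eventWindow(length(mi), fs, ev$onset_s[r], ev$duration_s[r], tailS)
      if (!length(idx)) return(NA_real_)
      max(mi[idx])
    }, numeric(1))
    out[[paste0(g, "_mag")]] <- mean(maxima, na.rm = TRUE)
  }
  auc <- sum(vapply(seq_len(nrow(ev)), function(r) {
    idx <- eventWindow(length(mi), fs, ev$onset_s[r], ev$duration_s[r], tailS)
    if (length(idx) < 2L) return(0)
    pracma::trapz(idx / fs, mi[idx])
  }, numeric(1)))
  c(out, list(startle_auc = auc))
}

#' Per-well stimulus response magnitudes
#'
#' For each stimulus modality, the response magnitude is the mean over
#' events of the maximum motion index within the event window (onset to
#' onset + duration, plus a post-stimulus tail, default 1 s, since startle
#' responses outlast a 70 ms tap). `startle_auc` is the summed trapezoidal
#' integral of MI over all stimulus windows. Modalities with no events in
#' the battery are reported as `NA` (absent), never as zero.
#'
#' @param x a [ProfileSet-class], or a numeric MI series.
#' @param train a [StimulusTrain-class] (required for numeric `x`).
#' @param fs sampling rate (Hz; taken from the ProfileSet when available).
#' @param tailS post-stimulus tail included in event windows (s).
#' @return a `data.frame` with one row per well: `well_id`, `acoustic_mag`,
#'   `violet_mag`, `startle_auc`.
#' @export
#' @rdname responseMagnitudes
setMethod("responseMagnitudes", "ProfileSet",
  function(x, tailS = 1, ...) {
    mi <- miMatrix(x)
    fs <- frameRate(x)
    train <- stimulusTrain(x)
    res <- lapply(seq_len(ncol(mi)), function(j)
      .magnitudesOne(mi[, j], train, fs, tailS))
    data.frame(
      well_id = wellData(x)$well_id,
      acoustic_mag = vapply(res, `[[`, numeric(1), "acoustic_mag"),
      violet_mag = vapply(res, `[[`, numeric(1), "violet_mag"),
      startle_auc = vapply(res, `[[`, numeric(1), "startle_auc")
    )
  })

#' @rdname responseMagnitudes
#' @export
setMethod("responseMagnitudes", "numeric",
  function(x, train, fs = 25, tailS = 1, ...) {
    as.data.frame(.magnitudesOne(x, train, fs, tailS))
  })

#' Z-score a vector of response magnitudes across wells
#'
#' Standardizes with the sample (n - 1) standard deviation,
#' `z = (x - mean) / SD`, then min-max rescales the z-scores to `[0, 1]`.
#'
#' @param x numeric vector of per-well magnitudes (length >= 2).
#' @return list with components `z` and `normalized`.
#' @examples
#' zscoreNormalize(c(1, 2, 3))  # z = -1, 0, 1; normalized = 0, 0.5, 1
#' @export
zscoreNormalize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 wells")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate input: zero standard deviation")
  z <- (x - mean(x)) / s
  list(z = z, normalized = (z - min(z)) / (max(z) - min(z)))
}
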