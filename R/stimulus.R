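#' Construct a stimulus train
#'
#' Builds the timed battery of assay events that behavioral profiles are
#' aligned to. Events are sorted by onset; each assay segment must last
#' 30--120 s and every event must end within the battery.
#'
#' @param events `data.frame` with columns `type`, `onset_s`, `duration_s`,
#'   `amplitude`.
#' @param totalDuration total battery duration (s).
#' @param assayBounds interior boundaries (s) splitting the battery into
#'   assay segments; `numeric(0)` for a single assay.
#' @return a [StimulusTrain-class].
#' @examples
#' taps <- data.frame(type = "acoustic_low", onset_s = c(5, 15, 25),
#'                    duration_s = 0.07, amplitude = 1)
#' StimulusTrain(taps, totalDuration = 40)
#' @export
StimulusTrain <- function(events, totalDuration, assayBounds = numeric(0)) {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    stop("invalid stimulus config: at least one event is required")
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  new("StimulusTrain", events = events, totalDuration = as.numeric(totalDuration),
      assayBounds = as.numeric(assayBounds))
}

#' Default two-assay battery
#'
#' The standard screening battery: a 60 s acoustic assay with 6 low-amplitude
#' taps at 10 s spacing, followed by a 60 s photomotor assay with 3 violet
#' light pulses (10 s on / 10 s off). Total duration 120 s.
#'
#' @param tapOnset onset of the first tap (s).
#' @param tapSpacing spacing between taps (s).
#' @param tapDuration tap duration (s); the physical tap is a 70 ms event.
#' @return a [StimulusTrain-class] with 6 `acoustic_low` and 3 `violet` events.
#' @export
defaultBattery <- function(tapOnset = 5, tapSpacing = 10, tapDuration = 0.07) {
  taps <- data.frame(
    type = "acoustic_low",
    onset_s = tapOnset + tapSpacing * (0:5),
    duration_s = tapDuration,
    amplitude = 1
  )
  violet <- data.frame(
    type = "violet",
    onset_s = c(65, 85, 105),
    duration_s = 10,
    amplitude = 1
  )
  StimulusTrain(rbind(taps, violet), totalDuration = 120, assayBounds = 60)
}

#' @rdname accessors
#' @export
setMethod("stimulusEvents", "StimulusTrain", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("frameRate", "ProfileSet", function(x) metadata(x)$frameRate)

#' @rdname accessors
#' @export
setMethod("stimulusTrain", "ProfileSet", function(x) metadata(x)$stimulusTrain)

setMethod("show", "StimulusTrain", function(object) {
  ev <- object@events
  cat("StimulusTrain:", nrow(ev), "events over", object@totalDuration, "s\n")
  tab <- table(ev$type)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
})

#' Sample indices covered by a stimulus event window
#'
#' Motion-index sample `i` carries the timestamp of frame `i + 1`, i.e.
#' `i / fs` seconds with the first video frame at time 0. Windows are
#' half-open `[onset, onset + duration + tail)`; the optional tail captures
#' startle responses that outlast a brief tap.
#'
#' @param n series length.
#' @param fs sampling rate (Hz).
#' @param onsetS,durationS event onset and duration (s).
#' @param tailS post-stimulus tail included in the window (s).
#' @return integer vector of sample indices (possibly empty).
#' @keywords internal
eventWindow <- function(n, fs, onsetS, durationS, tailS = 0) {
  t <- seq_len(n) / fs
  which(t >= onsetS - 1e-9 & t < onsetS + durationS + tailS - 1e-9)
}
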