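#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Stimulus train: the timed battery of assay events
#'
#' A `StimulusTrain` holds the typed, timed stimulus events (acoustic taps,
#' light pulses) that define an assay battery, together with the battery's
#' total duration. Events are kept sorted by onset.
#'
#' @slot events a `data.frame` with columns `type` (one of `acoustic_low`,
#'   `acoustic_hard`, `violet`, `blue`, `red`), `onset_s`, `duration_s`,
#'   `amplitude`.
#' @slot totalDuration total battery duration in seconds.
#' @slot assayBounds numeric vector of assay segment boundaries in seconds
#'   (used only for display; each segment must last 30--120 s).
#'
#' @seealso [stimulusTrain()], [defaultBattery()]
#' @exportClass StimulusTrain
setClass("StimulusTrain",
  representation(
    events = "data.frame",
    totalDuration = "numeric",
    assayBounds = "numeric"
  )
)

setValidity("StimulusTrain", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("type", "onset_s", "duration_s", "amplitude")
  if (!all(need %in% names(ev))) {
    return(paste("events must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(ev) == 0L) msgs <- c(msgs, "a stimulus train must contain at least one event")
  ok_types <- c("acoustic_low", "acoustic_hard", "violet", "blue", "red")
  if (nrow(ev) > 0L && !all(ev$type %in% ok_types)) {
    msgs <- c(msgs, paste("event types must be in:", paste(ok_types, collapse = ", ")))
  }
  if (nrow(ev) > 1L && is.unsorted(ev$onset_s)) {
    msgs <- c(msgs, "events must be sorted by onset")
  }
  if (length(object@totalDuration) != 1L || object@totalDuration <= 0) {
    msgs <- c(msgs, "totalDuration must be a positive scalar")
  }
  if (nrow(ev) > 0L && any(ev$onset_s + ev$duration_s > object@totalDuration + 1e-9)) {
    msgs <- c(msgs, "every event must end within totalDuration")
  }
  segs <- diff(c(0, object@assayBounds, object@totalDuration))
  if (any(segs < 30 - 1e-9 | segs > 120 + 1e-9)) {
    msgs <- c(msgs, "each assay segment must last between 30 and 120 seconds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of behavioral profiles (well x time motion-index matrix)
#'
#' `ProfileSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' mandatory `mi` assay (rows = time bins, columns = wells), per-well column
#' data (`well_id`, `plate_id`, `treatment`, `concentration_uM`, `n_fish`),
#' and the [StimulusTrain-class] plus sampling rate stored in `metadata()`.
#' All motion-index values are non-negative by construction.
#'
#' @seealso [ProfileSet()], [miMatrix()], [stimulusTrain()]
#' @exportClass ProfileSet
setClass("ProfileSet", contains = "SummarizedExperiment")

setValidity("ProfileSet", function(object) {
  msgs <- character()
  if (!"mi" %in% assayNames(object)) msgs <- c(msgs, "assay 'mi' is required")
  else {
    mi <- assay(object, "mi")
    if (any(!is.finite(mi))) msgs <- c(msgs, "all motion-index values must be finite")
    else if (any(mi < 0)) msgs <- c(msgs, "all motion-index values must be >= 0")
  }
  need <- c("well_id", "treatment", "concentration_uM")
  miss <- setdiff(need, names(colData(object)))
  if (length(miss)) msgs <- c(msgs, paste("colData lacks:", paste(miss, collapse = ", ")))
  md <- metadata(object)
  if (is.null(md$stimulusTrain) || !is(md$stimulusTrain, "StimulusTrain")) {
    msgs <- c(msgs, "metadata()$stimulusTrain must be a StimulusTrain")
  }
  if (is.null(md$frameRate) || md$frameRate <= 0) {
    msgs <- c(msgs, "metadata()$frameRate must be a positive sampling rate (Hz)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Archetype reference profile selected by simulated annealing
#'
#' The averaged motion-index profile of the replicate positive-control wells
#' selected by [selectReference()], together with the selected member well
#' ids, the achieved objective value, and a snapshot of the annealing
#' configuration.
#'
#' @slot profile averaged motion-index series.
#' @slot memberIds character vector of the selected member wells.
#' @slot objectiveValue achieved value of the subset objective.
#' @slot annealConfig list snapshot of the [annealConfig()] used.
#' @slot frameRate sampling rate of the profile (Hz).
#'
#' @exportClass ReferenceProfile
setClass("ReferenceProfile",
  representation(
    profile = "numeric",
    memberIds = "character",
    objectiveValue = "numeric",
    annealConfig = "list",
    frameRate = "numeric"
  )
)

setValidity("ReferenceProfile", function(object) {
  msgs <- character()
  if (length(object@profile) < 2L) msgs <- c(msgs, "profile must have length >= 2")
  if (any(!is.finite(object@profile))) msgs <- c(msgs, "profile must be finite")
  k <- object@annealConfig$subsetSize
  if (!is.null(k) && length(object@memberIds) != k) {
    msgs <- c(msgs, "member count must equal the configured subset size")
  }
  if (length(msgs)) msgs else TRUE
})

#' Compound library with fingerprints, annotations and ground truth
#'
#' Container for a (synthetic or imported) screening library: a binary
#' fingerprint matrix (one row per compound), optional target annotations,
#' and -- for synthetic libraries -- a truth table recording the planted
#' cluster membership, phenotype class and dose law of every compound.
#'
#' @slot fingerprints integer 0/1 matrix, rownames = compound ids; constant
#'   width within a library.
#' @slot annotations `data.frame` with columns `compound_id`, `target_id`.
#' @slot truth `data.frame` keyed by `compound_id` (planted cluster/class/
#'   dose-law parameters; empty for imported libraries).
#'
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
  representation(
    fingerprints = "matrix",
    annotations = "data.frame",
    truth = "data.frame"
  )
)

setValidity("CompoundLibrary", function(object) {
  fp <- object@fingerprints
  msgs <- character()
  if (is.null(rownames(fp))) msgs <- c(msgs, "fingerprints must have compound ids as rownames")
  if (length(fp) && !all(fp %in% c(0L, 1L))) msgs <- c(msgs, "fingerprints must be binary (0/1)")
  if (nrow(object@truth) && !"compound_id" %in% names(object@truth)) {
    msgs <- c(msgs, "truth table must have a compound_id column")
  }
  if (nrow(object@annotations) &&
      !all(c("compound_id", "target_id") %in% names(object@annotations))) {
    msgs <- c(msgs, "annotations must have compound_id and target_id columns")
  }
  if (length(msgs)) msgs else TRUE
})
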