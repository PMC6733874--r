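#' Construct a ProfileSet from a motion-index matrix
#'
#' @param mi numeric matrix of motion-index values, rows = time bins,
#'   columns = wells. All values must be finite and non-negative.
#' @param wellInfo `data.frame`/`DataFrame` of per-well metadata with at
#'   least `well_id`, `treatment` and `concentration_uM`; one row per column
#'   of `mi`.
#' @param train the [StimulusTrain-class] the profiles are aligned to.
#' @param frameRate sampling rate in Hz (the video frame rate; default 25).
#' @return a [ProfileSet-class].
#' @examples
#' tr <- defaultBattery()
#' mi <- matrix(abs(rnorm(3000 * 2)), ncol = 2)
#' info <- data.frame(well_id = c("A01", "A02"), treatment = "DMSO",
#'                    concentration_uM = 0)
#' ps <- ProfileSet(mi, info, tr)
#' @export
ProfileSet <- function(mi, wellInfo, train, frameRate = 25) {
  mi <- as.matrix(mi)
  wellInfo <- as(as.data.frame(wellInfo), "DataFrame")
  if (nrow(wellInfo) != ncol(mi)) {
    stop("wellInfo must have one row per well (column of mi)")
  }
  if (!"plate_id" %in% names(wellInfo)) wellInfo$plate_id <- "P1"
  if (!"n_fish" %in% names(wellInfo)) wellInfo$n_fish <- 8L
  colnames(mi) <- wellInfo$well_id
  se <- SummarizedExperiment(
    assays = list(mi = mi),
    colData = wellInfo,
    rowData = DataFrame(t_s = seq_len(nrow(mi)) / frameRate),
    metadata = list(stimulusTrain = train, frameRate = frameRate)
  )
  new("ProfileSet", se)
}

#' @rdname accessors
#' @export
setMethod("miMatrix", "ProfileSet", function(x) assay(x, "mi"))

#' @rdname accessors
#' @export
setMethod("wellData", "ProfileSet", function(x) colData(x))

#' @rdname accessors
#' @export
setMethod("degenerateWells", "ProfileSet", function(x) {
  apply(assay(x, "mi"), 2L, function(v) all(v == 0) || stats::sd(v) == 0)
})

#' @rdname accessors
#' @export
setMethod("nmiMatrix", "ProfileSet", function(x) {
  apply(assay(x, "mi"), 2L, normalizeMotionIndex, degenerateOK = TRUE)
})

setMethod("show", "ProfileSet", function(object) {
  cat("ProfileSet:", ncol(object), "wells x", nrow(object), "time bins @",
      metadata(object)$frameRate, "Hz\n")
  tr <- table(colData(object)$treatment)
  top <- utils::head(sort(tr, decreasing = TRUE), 5)
  cat("  treatments:", paste0(names(top), " (", as.integer(top), ")",
                              collapse = ", "),
      if (length(tr) > 5) "...\n" else "\n")
})

#' Write / read a ProfileSet as a long-format delimited table
#'
#' The on-disk dialect is one row per (well, time bin):
#' `well_id, plate_id, treatment, concentration_uM, t_s, mi`. The stimulus
#' train travels alongside as a small JSON sidecar (same path with extension
#' `.train.json`) so that round-trips preserve alignment.
#'
#' @param x a [ProfileSet-class].
#' @param path CSV file path.
#' @return `readProfileCSV` returns a [ProfileSet-class];
#'   `writeProfileCSV` returns `path` invisibly.
#' @export
writeProfileCSV <- function(x, path) {
  mi <- miMatrix(x)
  cd <- as.data.frame(wellData(x))
  long <- data.frame(
    well_id = rep(cd$well_id, each = nrow(mi)),
    plate_id = rep(cd$plate_id, each = nrow(mi)),
    treatment = rep(cd$treatment, each = nrow(mi)),
    concentration_uM = rep(cd$concentration_uM, each = nrow(mi)),
    t_s = rep(seq_len(nrow(mi)) / frameRate(x), times = ncol(mi)),
    mi = as.vector(mi)
  )
  utils::write.csv(long, path, row.names = FALSE)
  tr <- stimulusTrain(x)
  side <- list(
    frameRate = frameRate(x),
    totalDuration = tr@totalDuration,
    assayBounds = tr@assayBounds,
    events = stimulusEvents(tr)
  )
  jsonlite::write_json(side, paste0(path, ".train.json"), digits = NA)
  invisible(path)
}

#' @rdname writeProfileCSV
#' @export
readProfileCSV <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".train.json"), simplifyVector = TRUE)
  train <- StimulusTrain(as.data.frame(side$events),
                         totalDuration = side$totalDuration,
                         assayBounds = side$assayBounds)
  wells <- unique(long$well_id)
  mi <- vapply(wells, function(w) long$mi[long$well_id == w],
               numeric(sum(long$well_id == wells[1L])))
  info <- long[match(wells, long$well_id),
               c("well_id", "plate_id", "treatment", "concentration_uM")]
  ProfileSet(mi, info, train, frameRate = side$frameRate)
}
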