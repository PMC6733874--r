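#' @rdname phenoscore
#' @export
setGeneric("phenoscore", function(x, reference, ...) standardGeneric("phenoscore"))

#' @rdname responseMagnitudes
#' @export
setGeneric("responseMagnitudes", function(x, ...) standardGeneric("responseMagnitudes"))

#' @rdname immobilizationIndex
#' @export
setGeneric("immobilizationIndex", function(x, dmsoStats, ...) standardGeneric("immobilizationIndex"))

#' Accessors for ProfileSet, ReferenceProfile and CompoundLibrary objects
#'
#' `miMatrix()` returns the time x well motion-index matrix; `nmiMatrix()`
#' the per-well normalized series (fully immobilized wells normalize to all
#' zeros and are flagged via [degenerateWells()]); `stimulusTrain()` the
#' battery; `frameRate()` the sampling rate in Hz; `wellData()` the per-well
#' column data; `referenceSeries()`, `memberIds()` and `objectiveValue()`
#' the slots of a [ReferenceProfile-class]; `fingerprints()`,
#' `annotations()` and `libraryTruth()` the slots of a
#' [CompoundLibrary-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("miMatrix", function(x) standardGeneric("miMatrix"))

#' @rdname accessors
#' @export
setGeneric("nmiMatrix", function(x) standardGeneric("nmiMatrix"))

#' @rdname accessors
#' @export
setGeneric("stimulusTrain", function(x) standardGeneric("stimulusTrain"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("wellData", function(x) standardGeneric("wellData"))

#' @rdname accessors
#' @export
setGeneric("degenerateWells", function(x) standardGeneric("degenerateWells"))

#' @rdname accessors
#' @export
setGeneric("stimulusEvents", function(x) standardGeneric("stimulusEvents"))

#' @rdname accessors
#' @export
setGeneric("referenceSeries", function(x) standardGeneric("referenceSeries"))

#' @rdname accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("libraryTruth", function(x) standardGeneric("libraryTruth"))
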