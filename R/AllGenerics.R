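#' @include AllClasses.R
NULL

#' Accessors for spectra and runs
#'
#' Standard read accessors for the slot contents of [Spectrum],
#' [BinnedSpectrum], [MsRun] and [RunDistanceMatrix] objects.
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("scanNumber", function(object) standardGeneric("scanNumber"))

#' @rdname accessors
#' @export
setGeneric("retentionTime", function(object) standardGeneric("retentionTime"))

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname accessors
#' @export
setGeneric("precursorCharge", function(object) standardGeneric("precursorCharge"))

#' @rdname accessors
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))

#' @rdname accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname accessors
#' @export
setGeneric("runLabels", function(object) standardGeneric("runLabels"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("binIndex", function(object) standardGeneric("binIndex"))
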