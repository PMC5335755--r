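#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("mz", "Spectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("scanNumber", "Spectrum", function(object) object@scanNumber)

#' @rdname accessors
#' @export
setMethod("retentionTime", "Spectrum", function(object) object@retentionTime)

#' @rdname accessors
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @rdname accessors
#' @export
setMethod("precursorCharge", "Spectrum", function(object) object@precursorCharge)

#' @rdname accessors
#' @export
setMethod("peakCount", "Spectrum", function(object) length(object@mz))

## BinnedSpectrum: representative m/z per occupied bin is (n* + 0.5) * bin
#' @rdname accessors
#' @export
setMethod("mz", "BinnedSpectrum",
    function(object) (object@binIndex + 0.5) * object@binWidth)

#' @rdname accessors
#' @export
setMethod("intensity", "BinnedSpectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("binWidth", "BinnedSpectrum", function(object) object@binWidth)

#' @rdname accessors
#' @export
setMethod("binIndex", "BinnedSpectrum", function(object) object@binIndex)

#' @rdname accessors
#' @export
setMethod("scanNumber", "BinnedSpectrum", function(object) object@scanNumber)

#' @rdname accessors
#' @export
setMethod("retentionTime", "BinnedSpectrum", function(object) object@retentionTime)

#' @rdname accessors
#' @export
setMethod("precursorMz", "BinnedSpectrum", function(object) object@precursorMz)

#' @rdname accessors
#' @export
setMethod("precursorCharge", "BinnedSpectrum",
    function(object) object@precursorCharge)

#' @rdname accessors
#' @export
setMethod("peakCount", "BinnedSpectrum", function(object) length(object@binIndex))

#' @rdname accessors
#' @export
setMethod("runId", "MsRun", function(object) object@runId)

#' @rdname accessors
#' @export
setMethod("spectra", "MsRun", function(object) object@spectra)

#' @rdname accessors
#' @export
setMethod("nSpectra", "MsRun", function(object) length(object@spectra))

#' @rdname accessors
#' @export
setMethod("runLabels", "RunDistanceMatrix",
    function(object) rownames(object@values))

#' Extract the distance values of a RunDistanceMatrix
#'
#' @param x a [RunDistanceMatrix].
#' @param ... ignored.
#' @return The labelled numeric matrix.
#' @export
setMethod("as.matrix", "RunDistanceMatrix", function(x, ...) x@values)

setMethod("show", "Spectrum", function(object) {
    chg <- if (is.na(object@precursorCharge)) "unknown"
           else as.character(object@precursorCharge)
    cat(sprintf("Spectrum: scan %d, precursor m/z %.4f (charge %s), %d peaks\n",
                object@scanNumber, object@precursorMz, chg,
                length(object@mz)))
})

setMethod("show", "BinnedSpectrum", function(object) {
    cat(sprintf("BinnedSpectrum: scan %d, bin width %g Th, %d occupied bins\n",
                object@scanNumber, object@binWidth, length(object@binIndex)))
})

setMethod("show", "MsRun", function(object) {
    cat(sprintf("MsRun '%s' with %d MS2 spectra\n", object@runId,
                length(object@spectra)))
    if (length(object@spectra)) {
        sc <- vapply(object@spectra, slot, integer(1), "scanNumber")
        cat(sprintf("  scan numbers %d..%d\n", min(sc), max(sc)))
    }
})

setMethod("show", "DistanceSpec", function(object) {
    extra <- switch(object@name,
        angle = sprintf(" (epsilon = %g)", object@epsilon),
        hausdorff = sprintf(" (delta = %g, k = %g)", object@delta,
                            object@kRoot),
        "")
    cat(sprintf("DistanceSpec: %s%s\n", object@name, extra))
})

setMethod("show", "MatchParams", function(object) {
    cat(sprintf(
        "MatchParams: topn = %s, bin = %g, ret = %g, prec = %g ppm, dist = %s, cdis = %g\n",
        ifelse(is.infinite(object@topn), "Inf", format(object@topn)),
        object@bin, object@ret, object@prec, object@dist@name, object@cdis))
})

setMethod("show", "RunDistanceMatrix", function(object) {
    n <- nrow(object@values)
    cat(sprintf("RunDistanceMatrix for %d runs\n", n))
    print(round(object@values, 4))
})

setMethod("show", "PermanovaResult", function(object) {
    cat("One-way PERMANOVA on run distances\n")
    cat(sprintf("  runs: %d, groups: %d\n", object@nRuns, object@nGroups))
    cat(sprintf("  SS total   = %.6g\n", object@ssTotal))
    cat(sprintf("  SS between = %.6g\n", object@ssBetween))
    cat(sprintf("  SS within  = %.6g\n", object@ssWithin))
    cat(sprintf("  pseudo-F   = %.6g\n", object@pseudoF))
    cat(sprintf("  partial R2 = %.6g\n", object@partialR2))
    if (!is.na(object@pValue))
        cat(sprintf("  p-value    = %.6g (%d permutations)\n", object@pValue,
                    object@nPermutations))
})

setMethod("show", "ModeSpec", function(object) {
    cat(sprintf(
        "ModeSpec: search = %s, universe = %s, annotation check = %s, filter check = %s, duplicates = %s\n",
        object@searchMethod, object@universe, object@annotationCheck,
        object@filterCheck, object@duplicates))
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(
        "SyntheticConfig: %d species x %d replicates, %d spectra/run, seed %d\n",
        object@nSpecies, object@replicatesPerSpecies, object@spectraPerRun,
        object@seed))
})
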