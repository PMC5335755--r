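#' @import methods
NULL

#' Spectrum: a single centroided MS2 scan
#'
#' One tandem mass spectrum: a peak list (m/z values sorted ascending with
#' their intensities) plus precursor information. The number of peaks of a
#' spectrum is available via [peakCount()]. An unknown precursor charge is
#' represented as `NA_integer_`.
#'
#' @slot scanNumber positive integer scan index within the acquisition.
#' @slot retentionTime scan start time in seconds, `NA_real_` when absent.
#' @slot precursorMz precursor mass-to-charge ratio (Th).
#' @slot precursorCharge integer precursor charge state, `NA_integer_` =
#'   unknown.
#' @slot mz numeric vector of fragment m/z values, strictly ascending.
#' @slot intensity numeric vector of non-negative peak intensities, same
#'   length as `mz`.
#'
#' @seealso [MsRun], [binPeaks()], [selectTopPeaks()]
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        scanNumber = "integer",
        retentionTime = "numeric",
        precursorMz = "numeric",
        precursorCharge = "integer",
        mz = "numeric",
        intensity = "numeric"
    ),
    prototype(
        scanNumber = 1L,
        retentionTime = NA_real_,
        precursorMz = NA_real_,
        precursorCharge = NA_integer_,
        mz = numeric(),
        intensity = numeric()
    )
)

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@scanNumber) != 1L || is.na(object@scanNumber) ||
        object@scanNumber < 1L)
        msg <- c(msg, "scanNumber must be a single positive integer")
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "mz must be strictly ascending")
    if (any(object@intensity < 0))
        msg <- c(msg, "intensities must be non-negative")
    if (length(object@precursorMz) != 1L)
        msg <- c(msg, "precursorMz must be a single value")
    if (!is.na(object@precursorCharge) && object@precursorCharge < 1L)
        msg <- c(msg, "precursorCharge must be >= 1 or NA (unknown)")
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted ascending by m/z; exact duplicate m/z values are collapsed
#' to their maximum intensity so that the sortedness invariant is strict.
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param scanNumber positive integer.
#' @param precursorMz precursor m/z (Th).
#' @param precursorCharge integer charge or `NA` for unknown.
#' @param retentionTime seconds, or `NA`.
#' @return A [Spectrum] object.
#' @examples
#' s <- Spectrum(mz = c(300.1, 120.2), intensity = c(5, 2),
#'               scanNumber = 7, precursorMz = 512.3, precursorCharge = 2)
#' peakCount(s)
#' @export
Spectrum <- function(mz = numeric(), intensity = numeric(), scanNumber = 1L,
                     precursorMz = NA_real_, precursorCharge = NA_integer_,
                     retentionTime = NA_real_) {
    mz <- as.numeric(mz)
    intensity <- as.numeric(intensity)
    if (length(mz) != length(intensity))
        stop("mz and intensity must have equal length")
    if (is.unsorted(mz, strictly = TRUE)) {
        o <- order(mz)
        mz <- mz[o]
        intensity <- intensity[o]
        if (anyDuplicated(mz)) {
            intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), max))
            mz <- unique(mz)
        }
    }
    new("Spectrum", scanNumber = as.integer(scanNumber),
        retentionTime = as.numeric(retentionTime),
        precursorMz = as.numeric(precursorMz),
        precursorCharge = as.integer(precursorCharge),
        mz = mz, intensity = intensity)
}

#' BinnedSpectrum: a spectrum after fixed-width m/z binning
#'
#' Sparse representation of a binned spectrum: each occupied bin with index
#' \eqn{n^*} covers the half-open interval \eqn{[n^* \cdot bin, (n^*+1) \cdot
#' bin)} and carries the maximum intensity of the peaks assigned to it; its
#' representative m/z is \eqn{(n^*+0.5)\cdot bin}. Precursor fields are
#' inherited from the source [Spectrum].
#'
#' @slot binWidth bin width in Th.
#' @slot binIndex non-negative integer bin indices, strictly ascending.
#' @slot intensity representative (maximum) intensity per occupied bin.
#' @slot scanNumber,retentionTime,precursorMz,precursorCharge as in
#'   [Spectrum].
#' @seealso [binPeaks()]
#' @exportClass BinnedSpectrum
setClass("BinnedSpectrum",
    representation(
        binWidth = "numeric",
        binIndex = "integer",
        intensity = "numeric",
        scanNumber = "integer",
        retentionTime = "numeric",
        precursorMz = "numeric",
        precursorCharge = "integer"
    )
)

setValidity("BinnedSpectrum", function(object) {
    msg <- character()
    if (length(object@binWidth) != 1L || object@binWidth <= 0)
        msg <- c(msg, "binWidth must be a single positive value")
    if (length(object@binIndex) != length(object@intensity))
        msg <- c(msg, "binIndex and intensity must have equal length")
    if (length(object@binIndex) > 1L && any(diff(object@binIndex) <= 0L))
        msg <- c(msg, "binIndex must be strictly ascending")
    if (any(object@binIndex < 0L))
        msg <- c(msg, "bin indices must be non-negative")
    if (length(msg)) msg else TRUE
})

#' MsRun: an ordered collection of MS2 spectra from one LC-MS/MS acquisition
#'
#' Spectra are kept sorted by ascending scan number; the rank of a spectrum is
#' its 1-based position in this ordering. Scan numbers are unique within a
#' run.
#'
#' @slot runId character run identifier.
#' @slot spectra list of [Spectrum] objects ordered by scan number.
#' @exportClass MsRun
setClass("MsRun",
    representation(runId = "character", spectra = "list"),
    prototype(runId = "run", spectra = list())
)

setValidity("MsRun", function(object) {
    msg <- character()
    if (length(object@runId) != 1L || is.na(object@runId))
        msg <- c(msg, "runId must be a single string")
    if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
        msg <- c(msg, "spectra must all be Spectrum objects")
    else {
        sc <- vapply(object@spectra, slot, integer(1), "scanNumber")
        if (anyDuplicated(sc))
            msg <- c(msg, "scan numbers must be unique within a run")
        if (length(sc) > 1L && is.unsorted(sc, strictly = TRUE))
            msg <- c(msg, "spectra must be ordered by ascending scan number")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an MsRun
#'
#' @param spectra list of [Spectrum] objects; reordered by scan number.
#' @param runId run identifier.
#' @return An [MsRun] object.
#' @export
MsRun <- function(spectra = list(), runId = "run") {
    if (length(spectra)) {
        sc <- vapply(spectra, slot, integer(1), "scanNumber")
        spectra <- spectra[order(sc)]
    }
    new("MsRun", runId = as.character(runId), spectra = spectra)
}

#' DistanceSpec: choice and hyperparameters of the spectrum distance
#'
#' @slot name one of `"cos"`, `"angle"`, `"hausdorff"`.
#' @slot epsilon m/z match tolerance \eqn{\epsilon} (Th), angle distance only.
#' @slot delta error tolerance \eqn{\delta} (Th), Hausdorff only.
#' @slot kRoot root exponent \eqn{k \ge 1}, Hausdorff only.
#' @exportClass DistanceSpec
setClass("DistanceSpec",
    representation(name = "character", epsilon = "numeric",
                   delta = "numeric", kRoot = "numeric"),
    prototype(name = "cos", epsilon = 0.05, delta = 0.05, kRoot = 50)
)

setValidity("DistanceSpec", function(object) {
    msg <- character()
    if (!object@name %in% c("cos", "angle", "hausdorff"))
        msg <- c(msg, "name must be one of 'cos', 'angle', 'hausdorff'")
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
    if (object@kRoot < 1) msg <- c(msg, "kRoot must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a DistanceSpec
#'
#' Defaults follow the evaluated hyperparameter settings:
#' \eqn{\epsilon = 0.05}, \eqn{\delta = 0.05}, \eqn{k = 50}.
#'
#' @param name `"cos"`, `"angle"` or `"hausdorff"`.
#' @param epsilon angle match tolerance (Th).
#' @param delta Hausdorff error tolerance (Th).
#' @param kRoot Hausdorff root exponent.
#' @return A [DistanceSpec].
#' @export
distanceSpec <- function(name = c("cos", "angle", "hausdorff"),
                         epsilon = 0.05, delta = 0.05, kRoot = 50) {
    name <- match.arg(name)
    new("DistanceSpec", name = name, epsilon = epsilon, delta = delta,
        kRoot = kRoot)
}

#' MatchParams: the tunable parameters of the run-matching algorithm
#'
#' Houses the six tunables of the matching pipeline: `topn` (top-n peak
#' selection, `Inf` = keep all), `bin` (bin width, Th), `ret` (rank-window
#' half-width on scan-number ranks), `prec` (precursor mass tolerance, ppm),
#' `dist` (a [DistanceSpec]) and `cdis` (match cutoff on the spectrum
#' distance). Defaults are the optimized setting: `topn = Inf`, `bin = 0.2`,
#' `ret = 3000`, `prec = 10`, cosine distance, `cdis = 0.3`.
#'
#' @slot topn numeric, positive integer or `Inf`.
#' @slot bin positive bin width (Th).
#' @slot ret non-negative integer rank-window half-width.
#' @slot prec non-negative precursor tolerance in ppm.
#' @slot dist a [DistanceSpec].
#' @slot cdis positive distance cutoff.
#' @exportClass MatchParams
setClass("MatchParams",
    representation(topn = "numeric", bin = "numeric", ret = "numeric",
                   prec = "numeric", dist = "DistanceSpec", cdis = "numeric"),
    prototype(topn = Inf, bin = 0.2, ret = 3000, prec = 10, cdis = 0.3)
)

setValidity("MatchParams", function(object) {
    msg <- character()
    if (!(is.infinite(object@topn) || (object@topn >= 1 &&
          object@topn == round(object@topn))))
        msg <- c(msg, "topn must be a positive integer or Inf")
    if (object@bin <= 0) msg <- c(msg, "bin must be > 0")
    if (object@ret < 0 || (is.finite(object@ret) &&
        object@ret != round(object@ret)))
        msg <- c(msg, "ret must be a non-negative integer")
    if (object@prec < 0) msg <- c(msg, "prec must be >= 0")
    if (object@cdis <= 0) msg <- c(msg, "cdis must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct MatchParams
#'
#' @param topn positive integer or `Inf` (no selection).
#' @param bin bin width (Th).
#' @param ret rank-window half-width.
#' @param prec precursor tolerance (ppm).
#' @param dist a [DistanceSpec] (default cosine).
#' @param cdis distance cutoff for a match.
#' @return A [MatchParams] object.
#' @examples
#' matchParams()                      # the optimized default setting
#' matchParams(topn = 20, bin = 0.01, dist = distanceSpec("hausdorff"))
#' @export
matchParams <- function(topn = Inf, bin = 0.2, ret = 3000, prec = 10,
                        dist = distanceSpec("cos"), cdis = 0.3) {
    new("MatchParams", topn = as.numeric(topn), bin = bin,
        ret = as.numeric(ret), prec = prec, dist = dist, cdis = cdis)
}

#' RunDistanceMatrix: symmetric run-level distance matrix
#'
#' @slot values symmetric numeric matrix with run labels as dimnames; all
#'   entries in `[0, 1]`.
#' @exportClass RunDistanceMatrix
setClass("RunDistanceMatrix", representation(values = "matrix"))

setValidity("RunDistanceMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
        msg <- c(msg, "matrix must carry identical row/column run labels")
    if (anyDuplicated(rownames(v))) msg <- c(msg, "run labels must be unique")
    if (!isTRUE(all.equal(v, t(v), tolerance = 0)) && !identical(v, t(v)))
        msg <- c(msg, "matrix must be exactly symmetric")
    if (any(v < 0 | v > 1)) msg <- c(msg, "entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a RunDistanceMatrix
#'
#' @param values square symmetric numeric matrix, entries in `[0, 1]`.
#' @param labels optional run labels (defaults to existing dimnames).
#' @return A [RunDistanceMatrix].
#' @export
runDistanceMatrixFromValues <- function(values, labels = rownames(values)) {
    values <- as.matrix(values)
    if (is.null(labels)) labels <- paste0("run", seq_len(nrow(values)))
    dimnames(values) <- list(labels, labels)
    new("RunDistanceMatrix", values = values)
}

#' PermanovaResult: one-way PERMANOVA decomposition of a distance matrix
#'
#' @slot ssTotal,ssBetween,ssWithin sums of squares of distances.
#' @slot pseudoF pseudo-F ratio (`Inf` when the within sum of squares is 0).
#' @slot partialR2 between-group sum of squares over total.
#' @slot pValue permutation p-value, `NA` when no test was run.
#' @slot nPermutations number of random permutations used.
#' @slot nGroups,nRuns design dimensions.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
    representation(ssTotal = "numeric", ssBetween = "numeric",
                   ssWithin = "numeric", pseudoF = "numeric",
                   partialR2 = "numeric", pValue = "numeric",
                   nPermutations = "integer", nGroups = "integer",
                   nRuns = "integer"),
    prototype(pValue = NA_real_, nPermutations = 0L)
)

#' ModeSpec: one comparison mode of the annotation benchmark
#'
#' A comparison algorithm is a combination of search method (`database` hit =
#' same peptide annotated among candidates; `distance` hit = spectrum distance
#' below `cdis`), spectrum universe (`all` spectra or `reduced` to annotated
#' ones), an optional annotation check (both query and candidate must carry a
#' peptide annotation), an optional filter check (the rank-window / charge /
#' ppm candidate constraints), and duplicate handling (`kept`, or `removed` =
#' score unique peptide hitlists; database search only).
#'
#' @slot searchMethod `"database"` or `"distance"`.
#' @slot universe `"all"` or `"reduced"`.
#' @slot annotationCheck logical.
#' @slot filterCheck logical.
#' @slot duplicates `"kept"` or `"removed"`.
#' @seealso [modeSpec()], [annotationModePresets()]
#' @exportClass ModeSpec
setClass("ModeSpec",
    representation(searchMethod = "character", universe = "character",
                   annotationCheck = "logical", filterCheck = "logical",
                   duplicates = "character"))

setValidity("ModeSpec", function(object) {
    msg <- character()
    if (!object@searchMethod %in% c("database", "distance"))
        msg <- c(msg, "searchMethod must be 'database' or 'distance'")
    if (!object@universe %in% c("all", "reduced"))
        msg <- c(msg, "universe must be 'all' or 'reduced'")
    if (!object@duplicates %in% c("kept", "removed"))
        msg <- c(msg, "duplicates must be 'kept' or 'removed'")
    if (object@duplicates == "removed" && object@searchMethod != "database")
        msg <- c(msg, "duplicates = 'removed' is only supported for the database search method")
    if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic multi-species generator
#'
#' Describes a synthetic dataset of `nSpecies` species measured in
#' `replicatesPerSpecies` technical replicates. Each species owns a library
#' of template spectra; replicates are noisy re-acquisitions of that library
#' (whole-spectrum dropout, fragment m/z jitter, lognormal intensity noise,
#' peak dropout, windowed retention-order shuffling), emulating
#' data-dependent acquisition variability.
#'
#' @slot nSpecies,replicatesPerSpecies,spectraPerRun integer design sizes.
#' @slot peaksPerSpectrum integer range (min, max) of peaks per template.
#' @slot mzRange fragment m/z interval (Th).
#' @slot precursorRange precursor m/z interval (Th).
#' @slot chargeWeights sampling weights for charges 2 and 3.
#' @slot precursorJitterPpm per-replicate precursor mass error (ppm sd).
#' @slot mzJitterSd fragment m/z jitter sd (Th).
#' @slot intensityNoiseCv coefficient of variation of lognormal intensity
#'   noise.
#' @slot peakDropoutRate per-peak dropout probability in `[0, 1)`.
#' @slot spectrumDropoutRate per-spectrum dropout probability in `[0, 1)`.
#' @slot sharedLibraryFraction fraction of templates drawn from a pool shared
#'   across species, in `[0, 1]`.
#' @slot retentionShuffleWindow window size for local retention-order
#'   shuffling.
#' @slot unannotatedFraction fraction of spectra left without a peptide
#'   annotation.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(nSpecies = "integer", replicatesPerSpecies = "integer",
                   spectraPerRun = "integer", peaksPerSpectrum = "integer",
                   mzRange = "numeric", precursorRange = "numeric",
                   chargeWeights = "numeric", precursorJitterPpm = "numeric",
                   mzJitterSd = "numeric", intensityNoiseCv = "numeric",
                   peakDropoutRate = "numeric", spectrumDropoutRate = "numeric",
                   sharedLibraryFraction = "numeric",
                   retentionShuffleWindow = "integer",
                   unannotatedFraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
    if (object@replicatesPerSpecies < 1L)
        msg <- c(msg, "replicatesPerSpecies must be >= 1")
    if (object@spectraPerRun < 1L) msg <- c(msg, "spectraPerRun must be >= 1")
    if (length(object@peaksPerSpectrum) != 2L ||
        object@peaksPerSpectrum[1] < 1L ||
        object@peaksPerSpectrum[2] < object@peaksPerSpectrum[1])
        msg <- c(msg, "peaksPerSpectrum must be an increasing (min, max) pair")
    for (nm in c("peakDropoutRate", "spectrumDropoutRate"))
        if (slot(object, nm) < 0 || slot(object, nm) >= 1)
            msg <- c(msg, paste(nm, "must lie in [0, 1)"))
    if (object@sharedLibraryFraction < 0 || object@sharedLibraryFraction > 1)
        msg <- c(msg, "sharedLibraryFraction must lie in [0, 1]")
    if (object@unannotatedFraction < 0 || object@unannotatedFraction > 1)
        msg <- c(msg, "unannotatedFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
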