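#' @include AllClasses.R
NULL

#' Keep only the top-n most intense peaks of a spectrum
#'
#' First preprocessing step of the matching pipeline: only the `topn` peaks
#' with highest intensity are retained (`topn = Inf` keeps all). Ties at the
#' `topn`-th intensity are broken in favour of the lower m/z peak, i.e. peaks
#' are ranked by (intensity descending, m/z ascending) and the first `topn`
#' kept. The result is re-sorted ascending by m/z.
#'
#' @param s a [Spectrum].
#' @param topn positive integer or `Inf`.
#' @return A [Spectrum] with at most `topn` peaks.
#' @examples
#' s <- Spectrum(mz = c(100, 200, 300), intensity = c(1, 9, 5))
#' mz(selectTopPeaks(s, 2))    # 200, 300
#' @export
selectTopPeaks <- function(s, topn = Inf) {
    stopifnot(is(s, "Spectrum"))
    if (length(topn) != 1L || is.na(topn) || topn <= 0 ||
        (is.finite(topn) && topn != round(topn)))
        stop("topn must be a positive integer or Inf")
    p <- length(s@mz)
    if (is.infinite(topn) || p <= topn)
        return(s)
    keep <- order(-s@intensity, s@mz)[seq_len(topn)]
    keep <- sort(keep)                      # mz already ascending
    initialize(s, mz = s@mz[keep], intensity = s@intensity[keep])
}

## bin index n* of an m/z value under width `bin`: half-open [n*bin, (n*+1)bin)
.binIndexOf <- function(x, bin) as.integer(floor(x / bin))

#' Bin a spectrum at fixed width
#'
#' All peaks with m/z in the half-open interval
#' \eqn{[n^* \cdot bin, (n^*+1) \cdot bin)} are replaced by one
#' representative: the maximum intensity placed at the central m/z value
#' \eqn{(n^*+0.5) \cdot bin}. A peak exactly on a bin boundary belongs to the
#' upper bin. Binning a spectrum's representatives again at the same width is
#' a no-op.
#'
#' @param s a [Spectrum].
#' @param bin positive bin width in Th.
#' @return A [BinnedSpectrum].
#' @examples
#' s <- Spectrum(mz = c(100.05, 100.12), intensity = c(3, 7))
#' b <- binPeaks(s, 0.2)
#' mz(b)           # 100.1
#' intensity(b)    # 7
#' @export
binPeaks <- function(s, bin) {
    stopifnot(is(s, "Spectrum"))
    if (length(bin) != 1L || is.na(bin) || bin <= 0)
        stop("bin must be a single positive value")
    if (length(s@mz) == 0L) {
        idx <- integer()
        int <- numeric()
    } else {
        raw <- .binIndexOf(s@mz, bin)
        idx <- unique(raw)                  # mz ascending => idx ascending
        int <- as.numeric(tapply(s@intensity, match(raw, idx), max))
    }
    new("BinnedSpectrum", binWidth = bin, binIndex = idx, intensity = int,
        scanNumber = s@scanNumber, retentionTime = s@retentionTime,
        precursorMz = s@precursorMz, precursorCharge = s@precursorCharge)
}

#' Preprocess a whole run for matching
#'
#' Applies [selectTopPeaks()] then [binPeaks()] to every spectrum of a run
#' and returns a compact list representation used by the matching engine.
#' Spectra emptied (or already empty) are flagged and never match.
#'
#' @param run an [MsRun].
#' @param params a [MatchParams] (only `topn` and `bin` are used).
#' @return A list with elements `runId`, `n`, `scan`, `premz`, `charge`
#'   (integer, `-1` codes unknown), `idx` (list of integer bin indices),
#'   `int` (list of intensities), `norm` (Euclidean norms of the binned
#'   intensities), `empty` (logical), `bin` (bin width).
#' @keywords internal
preprocessRun <- function(run, params) {
    stopifnot(is(run, "MsRun"), is(params, "MatchParams"))
    sp <- run@spectra
    n <- length(sp)
    idx <- vector("list", n)
    int <- vector("list", n)
    scan <- integer(n)
    premz <- numeric(n)
    charge <- integer(n)
    for (k in seq_len(n)) {
        b <- binPeaks(selectTopPeaks(sp[[k]], params@topn), params@bin)
        idx[[k]] <- b@binIndex
        int[[k]] <- b@intensity
        scan[k] <- b@scanNumber
        premz[k] <- b@precursorMz
        charge[k] <- if (is.na(b@precursorCharge)) -1L else b@precursorCharge
    }
    list(runId = run@runId, n = n, scan = scan, premz = premz,
         charge = charge, idx = idx, int = int,
         norm = vapply(int, function(v) sqrt(sum(v^2)), numeric(1)),
         empty = lengths(idx) == 0L, bin = params@bin)
}
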