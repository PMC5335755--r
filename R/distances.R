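#' @include preprocess.R
NULL

## ---- internal kernels on raw vectors (used by the matching engine) ----

## cosine distance between two sparse binned spectra given bin indices,
## intensities and precomputed Euclidean norms; NA when either is empty
.cosDist <- function(idxA, intA, normA, idxB, intB, normB) {
    if (length(idxA) == 0L || length(idxB) == 0L)
        return(NA_real_)
    m <- match(idxA, idxB)
    hit <- !is.na(m)
    if (!any(hit))
        return(1)
    1 - sum(intA[hit] * intB[m[hit]]) / (normA * normB)
}

## minimal absolute position difference from each element of a to the set b;
## both sorted ascending
.minAbsDiff <- function(a, b) {
    i <- findInterval(a, b)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(b))
    pmin(abs(a - b[lo]), abs(a - b[hi]))
}

## angle distance on peak position lists; NA when either is empty
.angleDist <- function(posA, posB, epsilon) {
    pA <- length(posA)
    pB <- length(posB)
    if (pA == 0L || pB == 0L)
        return(NA_real_)
    cnt <- sum(.minAbsDiff(posA, posB) <= epsilon)
    ratio <- cnt / sqrt(pA * pB)
    acos(min(max(ratio, 0), 1))   # clamp: several peaks of a may share one match in b
}

## directed Hausdorff mean term; NA when either side is empty
.hausdorffH <- function(posA, posB, delta, kRoot) {
    m <- .minAbsDiff(posA, posB)
    term <- ifelse(m > delta, m, 0)   # indicator kills tolerated differences
    mean(term^(1 / kRoot))            # 0^(1/k) = 0
}

.hausdorffDist <- function(posA, posB, delta, kRoot) {
    if (length(posA) == 0L || length(posB) == 0L)
        return(NA_real_)
    max(.hausdorffH(posA, posB, delta, kRoot),
        .hausdorffH(posB, posA, delta, kRoot))
}

## ---- user-facing distances on BinnedSpectrum objects ----

.checkBinnedPair <- function(a, b) {
    stopifnot(is(a, "BinnedSpectrum"), is(b, "BinnedSpectrum"))
    if (a@binWidth != b@binWidth)
        stop("spectra were binned at different widths (",
             a@binWidth, " vs ", b@binWidth, ")")
}

#' Cosine distance between two binned spectra
#'
#' One minus the cosine similarity of the binned intensity vectors: the dot
#' product over the union of occupied bins (an unoccupied bin contributes 0)
#' divided by the product of the Euclidean norms. Since intensities are
#' non-negative the result lies in `[0, 1]`.
#'
#' @param a,b [BinnedSpectrum] objects sharing the same bin width.
#' @return Distance in `[0, 1]`, or `NA_real_` when either spectrum has no
#'   occupied bin (undefined; callers treat this as "no match").
#' @examples
#' x <- binPeaks(Spectrum(mz = c(100.1, 100.3), intensity = c(1, 1)), 0.2)
#' y <- binPeaks(Spectrum(mz = 100.1, intensity = 1), 0.2)
#' cosineDistance(x, y)    # 1 - 1/sqrt(2)
#' @export
cosineDistance <- function(a, b) {
    .checkBinnedPair(a, b)
    .cosDist(a@binIndex, a@intensity, sqrt(sum(a@intensity^2)),
             b@binIndex, b@intensity, sqrt(sum(b@intensity^2)))
}

#' Angle distance between two spectra
#'
#' Intensity-free counterpart of the cosine distance on peak position lists:
#' \deqn{d_{angle}(a, b, \epsilon) = \arccos\left(\frac{\sum_q
#'   1\{\exists q^*: |x_{a,q} - x_{b,q^*}| \le \epsilon\}}
#'   {\sqrt{p_a \, p_b}}\right)}
#' The numerator counts, per peak of `a`, whether some peak of `b` lies
#' within `epsilon`; it can exceed the denominator when several peaks of `a`
#' share one partner in `b`, so the arccos argument is clamped to `[0, 1]`.
#' Applied after binning, positions are the representative bin centres.
#'
#' @param a,b [BinnedSpectrum] objects sharing the same bin width.
#' @param epsilon match tolerance in Th (default 0.05).
#' @return Distance in `[0, pi/2]`, or `NA_real_` when either spectrum is
#'   empty.
#' @export
angleDistance <- function(a, b, epsilon = 0.05) {
    .checkBinnedPair(a, b)
    if (epsilon < 0) stop("epsilon must be >= 0")
    .angleDist(mz(a), mz(b), epsilon)
}

#' Parametrized Hausdorff distance between two spectra
#'
#' For each peak of one spectrum take the minimal absolute m/z difference to
#' the other spectrum's peaks; differences at most `delta` are tolerated and
#' contribute 0, larger ones contribute their `kRoot`-th root. The directed
#' value averages these terms over the spectrum's peaks and the distance is
#' the maximum of the two directions. Applied after binning, positions are
#' the representative bin centres.
#'
#' @param a,b [BinnedSpectrum] objects sharing the same bin width.
#' @param delta error tolerance in Th (default 0.05).
#' @param kRoot root exponent `k >= 1` (default 50).
#' @return Non-negative distance, or `NA_real_` when either spectrum is
#'   empty.
#' @export
hausdorffDistance <- function(a, b, delta = 0.05, kRoot = 50) {
    .checkBinnedPair(a, b)
    if (delta < 0) stop("delta must be >= 0")
    if (kRoot < 1) stop("kRoot must be >= 1")
    .hausdorffDist(mz(a), mz(b), delta, kRoot)
}

#' Spectrum distance under a DistanceSpec
#'
#' Dispatches to [cosineDistance()], [angleDistance()] or
#' [hausdorffDistance()] according to `spec`. The cosine distance uses the
#' binned intensities; angle and Hausdorff use the representative peak
#' positions after the same binning, so all measures see identical
#' preprocessing.
#'
#' @param a,b [BinnedSpectrum] objects sharing the same bin width.
#' @param spec a [DistanceSpec].
#' @return Numeric distance, `NA_real_` when undefined.
#' @export
spectrumDistance <- function(a, b, spec = distanceSpec("cos")) {
    stopifnot(is(spec, "DistanceSpec"))
    switch(spec@name,
        cos = cosineDistance(a, b),
        angle = angleDistance(a, b, spec@epsilon),
        hausdorff = hausdorffDistance(a, b, spec@delta, spec@kRoot),
        stop("unknown distance name: ", spec@name))
}
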