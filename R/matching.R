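#' @include distances.R
NULL

## candidate ranks in a preprocessed run for a query with rank k, precursor
## m/z pm and coded charge ch; constraints checked in the printed order
## (a) rank window, (b) same charge, (c) precursor ppm
.candidates <- function(prepJ, k, pm, ch, ret, prec) {
    lo <- max(1, k - ret)
    hi <- min(prepJ$n, k + ret)
    if (lo > hi)
        return(integer())
    cand <- seq.int(lo, hi)
    cand <- cand[prepJ$charge[cand] == ch]
    if (length(cand)) {
        ppm <- abs(prepJ$premz[cand] - pm) / pm * 1e6
        cand <- cand[ppm <= prec]
    }
    cand
}

## distance between query spectrum (given as binned idx/int/norm/positions)
## and candidate l of prepJ, under distance spec
.pairDist <- function(spec, idxK, intK, normK, prepJ, l, bin) {
    idxL <- prepJ$idx[[l]]
    if (spec@name == "cos")
        return(.cosDist(idxK, intK, normK, idxL, prepJ$int[[l]],
                        prepJ$norm[l]))
    posK <- (idxK + 0.5) * bin
    posL <- (idxL + 0.5) * bin
    if (length(posK) == 0L || length(posL) == 0L)
        return(NA_real_)
    if (spec@name == "angle")
        .angleDist(posK, posL, spec@epsilon)
    else
        .hausdorffDist(posK, posL, spec@delta, spec@kRoot)
}

## directed distance d*(i, j) on preprocessed runs
.directedDistance <- function(prepI, prepJ, params) {
    if (prepI$n == 0L)
        stop("run '", prepI$runId, "' contains no spectra; d* is undefined")
    spec <- params@dist
    cdis <- params@cdis
    unmatched <- 0L
    for (k in seq_len(prepI$n)) {
        if (prepI$empty[k]) {               # emptied by preprocessing: no match
            unmatched <- unmatched + 1L
            next
        }
        cand <- .candidates(prepJ, k, prepI$premz[k], prepI$charge[k],
                            params@ret, params@prec)
        hit <- FALSE
        if (length(cand)) {
            idxK <- prepI$idx[[k]]
            intK <- prepI$int[[k]]
            normK <- prepI$norm[k]
            for (l in cand) {
                d <- .pairDist(spec, idxK, intK, normK, prepJ, l, params@bin)
                if (!is.na(d) && d < cdis) {    # strict: equality is no match
                    hit <- TRUE
                    break
                }
            }
        }
        if (!hit)
            unmatched <- unmatched + 1L
    }
    unmatched / prepI$n
}

#' Candidate spectra for matching
#'
#' Returns the ranks (1-based positions in scan-number order) of the spectra
#' of `runJ` that a query spectrum with rank `k` may be matched against,
#' checking three constraints in order: (a) rank within the window
#' `[k - ret, k + ret]`, so at most `2 * ret + 1` spectra remain; (b) equal
#' precursor charge state (a spectrum of unknown charge only matches unknown
#' charge); (c) precursor mass within `prec` ppm,
#' \eqn{|m_l - m_k| / m_k \cdot 10^6 \le prec}. An empty set is a legal
#' result and means "no match available".
#'
#' @param k rank of the query spectrum in its own run.
#' @param runJ an [MsRun], the run searched for candidates.
#' @param query the query [Spectrum] (or [BinnedSpectrum]); only its
#'   precursor m/z and charge are used.
#' @param params a [MatchParams].
#' @return Integer vector of ranks in `runJ`.
#' @export
candidateIndices <- function(k, runJ, query, params = matchParams()) {
    stopifnot(is(runJ, "MsRun"), is(params, "MatchParams"))
    prepJ <- preprocessRun(runJ, params)
    ch <- precursorCharge(query)
    .candidates(prepJ, k, precursorMz(query),
                if (is.na(ch)) -1L else as.integer(ch),
                params@ret, params@prec)
}

#' Directed run distance d*(i, j)
#'
#' The fraction of spectra of `runI` with no match in `runJ`. A spectrum is
#' matched when its candidate set (see [candidateIndices()]) is non-empty and
#' the minimal spectrum distance over the candidates is strictly below
#' `cdis`; spectra with an empty candidate set, or emptied by preprocessing,
#' count as unmatched. Not symmetric.
#'
#' @param runI,runJ [MsRun] objects.
#' @param params a [MatchParams].
#' @return Fraction in `[0, 1]`.
#' @export
directedRunDistance <- function(runI, runJ, params = matchParams()) {
    stopifnot(is(runI, "MsRun"), is(runJ, "MsRun"), is(params, "MatchParams"))
    .directedDistance(preprocessRun(runI, params),
                      preprocessRun(runJ, params), params)
}

#' Symmetric run distance d(i, j)
#'
#' The mean of the two directed distances,
#' \eqn{d(i,j) = (d^*(i,j) + d^*(j,i)) / 2}.
#'
#' @inheritParams directedRunDistance
#' @return Distance in `[0, 1]`.
#' @export
runDistance <- function(runI, runJ, params = matchParams()) {
    stopifnot(is(runI, "MsRun"), is(runJ, "MsRun"), is(params, "MatchParams"))
    prepI <- preprocessRun(runI, params)
    prepJ <- preprocessRun(runJ, params)
    (.directedDistance(prepI, prepJ, params) +
     .directedDistance(prepJ, prepI, params)) / 2
}

#' Run-level distance matrix
#'
#' Computes all \eqn{N (N - 1)} directed distances between the given runs and
#' fills the symmetric matrix \eqn{d(i,j) = (d^*(i,j) + d^*(j,i)) / 2} with a
#' zero diagonal.
#'
#' @param runs list of at least two [MsRun] objects with unique run ids.
#' @param params a [MatchParams].
#' @param verbose emit a progress message per run pair.
#' @return A [RunDistanceMatrix] labelled by run ids.
#' @examples
#' r1 <- Spectrum(mz = c(100, 200), intensity = c(1, 2), scanNumber = 1,
#'                precursorMz = 500, precursorCharge = 2)
#' runA <- MsRun(list(r1), "A")
#' runB <- MsRun(list(r1), "B")
#' as.matrix(runDistanceMatrix(list(runA, runB)))
#' @export
runDistanceMatrix <- function(runs, params = matchParams(), verbose = FALSE) {
    stopifnot(is.list(runs), length(runs) >= 2L,
              all(vapply(runs, is, logical(1), "MsRun")),
              is(params, "MatchParams"))
    ids <- vapply(runs, runId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate run ids: ", paste(ids[duplicated(ids)], collapse = ", "))
    preps <- lapply(runs, preprocessRun, params = params)
    N <- length(runs)
    d <- matrix(0, N, N, dimnames = list(ids, ids))
    for (i in seq_len(N - 1L)) {
        for (j in seq.int(i + 1L, N)) {
            dij <- .directedDistance(preps[[i]], preps[[j]], params)
            dji <- .directedDistance(preps[[j]], preps[[i]], params)
            d[i, j] <- d[j, i] <- (dij + dji) / 2
            if (verbose)
                message(sprintf("d(%s, %s) = %.4f", ids[i], ids[j], d[i, j]))
        }
    }
    new("RunDistanceMatrix", values = d)
}
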