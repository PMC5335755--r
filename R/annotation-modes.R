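#' @include matching.R
NULL

#' Construct a ModeSpec
#'
#' @param searchMethod `"database"` (hit = same peptide annotated among the
#'   candidates) or `"distance"` (hit = spectrum distance below `cdis`).
#' @param universe `"all"` spectra or `"reduced"` to annotated spectra.
#' @param annotationCheck require both query and candidate to be annotated.
#' @param filterCheck apply the rank-window / charge / ppm candidate
#'   constraints.
#' @param duplicates `"kept"`, or `"removed"` to score unique peptide
#'   hitlists (database search only).
#' @return A [ModeSpec].
#' @seealso [annotationModePresets()] for the six named presets.
#' @export
modeSpec <- function(searchMethod = c("distance", "database"),
                     universe = c("all", "reduced"),
                     annotationCheck = FALSE, filterCheck = TRUE,
                     duplicates = c("kept", "removed")) {
    new("ModeSpec", searchMethod = match.arg(searchMethod),
        universe = match.arg(universe),
        annotationCheck = isTRUE(annotationCheck),
        filterCheck = isTRUE(filterCheck),
        duplicates = match.arg(duplicates))
}

#' The six named comparison modes
#'
#' Named presets combining search method, spectrum universe, annotation
#' check, filter check and duplicate handling:
#' \describe{
#'   \item{DB.ra}{database search, reduced universe, annotation check, no
#'     filter, duplicates kept}
#'   \item{DB.ra.nodup}{as DB.ra but scoring unique peptide hitlists}
#'   \item{DISMS2.f}{distance search on all spectra with filter check —
#'     identical to [runDistanceMatrix()]}
#'   \item{DB.a}{database search on all spectra, annotation check, no filter}
#'   \item{DISMS2.af}{distance search on all spectra with both annotation
#'     and filter checks}
#'   \item{DB.af}{database search on all spectra with both checks}
#' }
#'
#' @return Named list of [ModeSpec] objects.
#' @export
annotationModePresets <- function() {
    list(
        DB.ra = modeSpec("database", "reduced", TRUE, FALSE, "kept"),
        DB.ra.nodup = modeSpec("database", "reduced", TRUE, FALSE, "removed"),
        DISMS2.f = modeSpec("distance", "all", FALSE, TRUE, "kept"),
        DB.a = modeSpec("database", "all", TRUE, FALSE, "kept"),
        DISMS2.af = modeSpec("distance", "all", TRUE, TRUE, "kept"),
        DB.af = modeSpec("database", "all", TRUE, TRUE, "kept"))
}

## peptide per spectrum of `run` (NA_character_ = unannotated)
.peptidesFor <- function(run, ann) {
    if (is.null(ann) || nrow(ann) == 0L)
        return(rep(NA_character_, length(run@spectra)))
    key <- paste(ann$run_id, ann$scan_number)
    sc <- vapply(run@spectra, slot, integer(1), "scanNumber")
    ann$peptide[match(paste(run@runId, sc), key)]
}

#' Restrict a run to a spectrum universe
#'
#' With `universe = "all"` the run is returned unchanged; with `"reduced"`
#' only spectra carrying a peptide annotation are retained, in the original
#' order, and ranks are recomputed from the reduced list.
#'
#' @param run an [MsRun].
#' @param ann annotation data.frame (`run_id`, `scan_number`, `peptide`), see
#'   [readAnnotations()].
#' @param universe `"all"` or `"reduced"`.
#' @return An [MsRun].
#' @export
spectrumUniverse <- function(run, ann, universe = c("all", "reduced")) {
    stopifnot(is(run, "MsRun"))
    universe <- match.arg(universe)
    if (universe == "all")
        return(run)
    keep <- !is.na(.peptidesFor(run, ann))
    new("MsRun", runId = run@runId, spectra = run@spectra[keep])
}

## generic directed no-hit engine on universe-applied runs
.directedNoHit <- function(runI, runJ, ann, mode, params) {
    if (mode@duplicates == "removed") {
        pepI <- unique(stats::na.omit(.peptidesFor(runI, ann)))
        pepJ <- unique(stats::na.omit(.peptidesFor(runJ, ann)))
        if (length(pepI) == 0L)
            stop("run '", runI@runId,
                 "' has no annotated peptides; directed fraction undefined")
        return(sum(!pepI %in% pepJ) / length(pepI))
    }
    nI <- length(runI@spectra)
    if (nI == 0L)
        stop("run '", runI@runId,
             "' contains no spectra; directed fraction undefined")
    pepsI <- .peptidesFor(runI, ann)
    pepsJ <- .peptidesFor(runJ, ann)
    annJ <- which(!is.na(pepsJ))
    distance <- mode@searchMethod == "distance"
    prepI <- preprocessRun(runI, params)
    prepJ <- preprocessRun(runJ, params)
    noHit <- 0L
    for (k in seq_len(nI)) {
        if (mode@annotationCheck && is.na(pepsI[k])) {
            noHit <- noHit + 1L             # unannotated query is downgraded
            next
        }
        if (!distance && is.na(pepsI[k])) { # database hit needs a query peptide
            noHit <- noHit + 1L
            next
        }
        cand <- if (mode@filterCheck)
            .candidates(prepJ, k, prepI$premz[k], prepI$charge[k],
                        params@ret, params@prec)
        else seq_len(prepJ$n)
        if (mode@annotationCheck)
            cand <- intersect(cand, annJ)
        hit <- FALSE
        if (length(cand)) {
            if (!distance) {
                hit <- pepsI[k] %in% pepsJ[cand]
            } else if (!prepI$empty[k]) {
                idxK <- prepI$idx[[k]]
                intK <- prepI$int[[k]]
                normK <- prepI$norm[k]
                for (l in cand) {
                    d <- .pairDist(params@dist, idxK, intK, normK, prepJ, l,
                                   params@bin)
                    if (!is.na(d) && d < params@cdis) {
                        hit <- TRUE
                        break
                    }
                }
            }
        }
        if (!hit)
            noHit <- noHit + 1L
    }
    noHit / nI
}

#' Directed no-hit fraction under a comparison mode
#'
#' Generalization of [directedRunDistance()] over the comparison-mode grid:
#' the spectrum universe is applied to both runs, then for every spectrum of
#' `runI` a candidate list in `runJ` is formed (all spectra, or the
#' constrained set when the mode has a filter check; restricted to annotated
#' spectra under an annotation check, which also downgrades unannotated
#' queries to "no hit"). A hit is a candidate annotated with the same
#' peptide (database search) or one at spectrum distance below `cdis`
#' (distance search). With `duplicates = "removed"` the runs are replaced by
#' their unique peptide hitlists and set membership is scored.
#'
#' @param runI,runJ [MsRun] objects (full runs; universes are applied
#'   internally).
#' @param ann annotation data.frame (`run_id`, `scan_number`, `peptide`).
#' @param mode a [ModeSpec].
#' @param params a [MatchParams].
#' @return The fraction of query spectra (or peptides) without a hit.
#' @examples
#' presets <- annotationModePresets()
#' presets[["DB.ra"]]
#' @export
directedNoHitFraction <- function(runI, runJ, ann, mode,
                                  params = matchParams()) {
    stopifnot(is(runI, "MsRun"), is(runJ, "MsRun"), is(mode, "ModeSpec"),
              is(params, "MatchParams"))
    validObject(mode)
    .directedNoHit(spectrumUniverse(runI, ann, mode@universe),
                   spectrumUniverse(runJ, ann, mode@universe),
                   ann, mode, params)
}

#' Distance matrix under a comparison mode
#'
#' Symmetrized means of the directed no-hit fractions,
#' \eqn{d(i,j) = (d^*(i,j) + d^*(j,i)) / 2}, with a zero diagonal. The
#' `DISMS2.f` preset reproduces [runDistanceMatrix()] exactly.
#'
#' @param runs list of [MsRun] objects with unique ids.
#' @param ann annotation data.frame.
#' @param mode a [ModeSpec].
#' @param params a [MatchParams].
#' @return A [RunDistanceMatrix].
#' @export
modeDistanceMatrix <- function(runs, ann, mode, params = matchParams()) {
    stopifnot(is.list(runs), length(runs) >= 2L,
              all(vapply(runs, is, logical(1), "MsRun")))
    ids <- vapply(runs, runId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate run ids: ", paste(ids[duplicated(ids)], collapse = ", "))
    reduced <- lapply(runs, spectrumUniverse, ann = ann,
                      universe = mode@universe)
    N <- length(runs)
    d <- matrix(0, N, N, dimnames = list(ids, ids))
    for (i in seq_len(N - 1L)) {
        for (j in seq.int(i + 1L, N)) {
            dij <- .directedNoHit(reduced[[i]], reduced[[j]], ann, mode, params)
            dji <- .directedNoHit(reduced[[j]], reduced[[i]], ann, mode, params)
            d[i, j] <- d[j, i] <- (dij + dji) / 2
        }
    }
    new("RunDistanceMatrix", values = d)
}
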