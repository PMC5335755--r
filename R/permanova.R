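#' @include matching.R
NULL

## within-group sum of squared distances, Anderson style:
## sum over groups of (1/n_g) * sum_{i<j in g} d_ij^2
.ssWithin <- function(d2, groups) {
    sw <- 0
    for (g in unique(groups)) {
        i <- which(groups == g)
        sw <- sw + sum(d2[i, i]) / (2 * length(i))
    }
    sw
}

.asDistValues <- function(d) {
    if (is(d, "RunDistanceMatrix")) d@values else as.matrix(d)
}

#' One-way PERMANOVA sums of squares on a distance matrix
#'
#' Non-parametric multivariate analysis of variance computed directly from
#' the distances: \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{SS_{between} = SS_{total} - SS_{within}}. The pseudo-F ratio is
#' \eqn{(SS_{between}/(g-1)) / (SS_{within}/(N-g))} (infinite when
#' \eqn{SS_{within} = 0}) and the partial R-squared is
#' \eqn{SS_{between}/SS_{total}} (0 when \eqn{SS_{total} = 0}).
#'
#' @param d a [RunDistanceMatrix] or symmetric numeric matrix.
#' @param groups group label per run (e.g. species of each technical
#'   replicate).
#' @return A [PermanovaResult] without a p-value.
#' @examples
#' m <- matrix(1, 4, 4) - diag(4)
#' dimnames(m) <- list(letters[1:4], letters[1:4])
#' m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0
#' res <- permanovaSS(m, c("g1", "g1", "g2", "g2"))
#' res@partialR2   # 1: groups perfectly separated
#' @export
permanovaSS <- function(d, groups) {
    v <- .asDistValues(d)
    N <- nrow(v)
    groups <- as.character(groups)
    if (length(groups) != N)
        stop("need one group label per run")
    g <- length(unique(groups))
    if (g < 2L)
        stop("PERMANOVA needs at least two groups")
    d2 <- v^2
    ssT <- sum(d2[upper.tri(d2)]) / N
    ssW <- .ssWithin(d2, groups)
    ssB <- ssT - ssW
    pseudoF <- if (ssW == 0) Inf else (ssB / (g - 1)) / (ssW / (N - g))
    new("PermanovaResult", ssTotal = ssT, ssBetween = ssB, ssWithin = ssW,
        pseudoF = pseudoF,
        partialR2 = if (ssT == 0) 0 else ssB / ssT,
        pValue = NA_real_, nPermutations = 0L, nGroups = as.integer(g),
        nRuns = as.integer(N))
}

#' PERMANOVA permutation test
#'
#' Monte-Carlo permutation test of group separation: group labels are
#' shuffled uniformly at random `nPerm` times and the p-value is
#' \eqn{(\#\{F_{perm} \ge F_{obs}\} + 1) / (nPerm + 1)}. Deterministic for a
#' given `seed`.
#'
#' @inheritParams permanovaSS
#' @param nPerm number of random permutations (default 10000).
#' @param seed integer RNG seed.
#' @return A [PermanovaResult] with a p-value.
#' @export
permanovaTest <- function(d, groups, nPerm = 10000, seed = 1) {
    res <- permanovaSS(d, groups)
    v <- .asDistValues(d)
    d2 <- v^2
    groups <- as.character(groups)
    N <- res@nRuns
    g <- res@nGroups
    ssT <- res@ssTotal
    fObs <- res@pseudoF
    count <- 0L
    fPerm <- function(ssW) if (ssW == 0) Inf
             else ((ssT - ssW) / (g - 1)) / (ssW / (N - g))
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    for (p in seq_len(nPerm)) {
        if (fPerm(.ssWithin(d2, sample(groups))) >= fObs)
            count <- count + 1L
    }
    initialize(res, pValue = (count + 1) / (nPerm + 1),
               nPermutations = as.integer(nPerm))
}

#' Factor levels of the two factorial evaluation designs
#'
#' Design 1 varies `topn` (20, 50, Inf), `bin` (0.01, 0.2), `ret` (1000,
#' 3000), `dist` (angle with \eqn{\epsilon = 0.05}, cosine, Hausdorff with
#' \eqn{\delta = 0.05, k = 50}) and `cdis` (0.1, 0.3) at `prec = 10` ppm: 72
#' combinations. Design 2 adds higher cutoffs for the (unbounded-in-`[0,1]`)
#' angle distance: `topn` (20, 50, Inf), `bin` 0.2, `ret` 3000, angle
#' distance, `cdis` (0.4, 0.5, 0.6): 9 combinations.
#'
#' @param design `"design1"`, `"design2"` or `"both"`.
#' @return A list of designs; each design is a named list of level vectors
#'   (with `dist` a list of [DistanceSpec] objects).
#' @export
factorialDesign <- function(design = c("both", "design1", "design2")) {
    design <- match.arg(design)
    d1 <- list(
        topn = c(20, 50, Inf),
        bin = c(0.01, 0.2),
        ret = c(1000, 3000),
        prec = 10,
        dist = list(distanceSpec("angle", epsilon = 0.05),
                    distanceSpec("cos"),
                    distanceSpec("hausdorff", delta = 0.05, kRoot = 50)),
        cdis = c(0.1, 0.3))
    d2 <- list(
        topn = c(20, 50, Inf),
        bin = 0.2,
        ret = 3000,
        prec = 10,
        dist = list(distanceSpec("angle", epsilon = 0.05)),
        cdis = c(0.4, 0.5, 0.6))
    switch(design,
        design1 = list(design1 = d1),
        design2 = list(design2 = d2),
        both = list(design1 = d1, design2 = d2))
}

#' Enumerate all parameter combinations of a factorial design
#'
#' Cartesian product of the factor levels of each design, designs
#' concatenated in order without deduplication. The level order follows the
#' design definition with `cdis` varying fastest.
#'
#' @param design output of [factorialDesign()] (default: both designs, 81
#'   combinations).
#' @return List of [MatchParams].
#' @examples
#' length(enumerateGrid(factorialDesign("design1")))   # 72
#' length(enumerateGrid())                              # 81
#' @export
enumerateGrid <- function(design = factorialDesign("both")) {
    out <- list()
    for (d in design) {
        grid <- expand.grid(cdis = seq_along(d$cdis),
                            dist = seq_along(d$dist),
                            prec = seq_along(d$prec),
                            ret = seq_along(d$ret),
                            bin = seq_along(d$bin),
                            topn = seq_along(d$topn))
        for (r in seq_len(nrow(grid))) {
            out[[length(out) + 1L]] <- matchParams(
                topn = d$topn[grid$topn[r]],
                bin = d$bin[grid$bin[r]],
                ret = d$ret[grid$ret[r]],
                prec = d$prec[grid$prec[r]],
                dist = d$dist[[grid$dist[r]]],
                cdis = d$cdis[grid$cdis[r]])
        }
    }
    out
}

#' Grid search: PERMANOVA-ranked parameter optimization
#'
#' Computes one run distance matrix per parameter combination of the design
#' and ranks the combinations by the partial R-squared of a one-way
#' PERMANOVA of the group labels (technical replicates within species),
#' descending; ties keep the grid order. With `nPerm > 0` a permutation
#' p-value is added per combination.
#'
#' @param runs list of [MsRun] objects.
#' @param groups group label per run.
#' @param design output of [factorialDesign()].
#' @param nPerm permutations for the p-value (0 = skip the test).
#' @param seed RNG seed for the permutation test.
#' @param verbose emit one message per combination.
#' @return A data.frame with columns `rank`, `topn`, `bin`, `ret`, `prec`,
#'   `dist`, `cdis`, `partialR2` (and `pValue` when `nPerm > 0`), ordered by
#'   rank.
#' @export
gridSearch <- function(runs, groups, design = factorialDesign("both"),
                       nPerm = 0, seed = 1, verbose = FALSE) {
    grid <- enumerateGrid(design)
    n <- length(grid)
    r2 <- numeric(n)
    pv <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        d <- runDistanceMatrix(runs, grid[[i]])
        res <- if (nPerm > 0) permanovaTest(d, groups, nPerm, seed)
               else permanovaSS(d, groups)
        r2[i] <- res@partialR2
        pv[i] <- res@pValue
        if (verbose)
            message(sprintf("setting %d/%d: partial R2 = %.4f", i, n, r2[i]))
    }
    distName <- vapply(grid, function(p) p@dist@name, character(1))
    tab <- data.frame(
        topn = vapply(grid, function(p) p@topn, numeric(1)),
        bin = vapply(grid, function(p) p@bin, numeric(1)),
        ret = vapply(grid, function(p) p@ret, numeric(1)),
        prec = vapply(grid, function(p) p@prec, numeric(1)),
        dist = distName,
        cdis = vapply(grid, function(p) p@cdis, numeric(1)),
        partialR2 = r2)
    if (nPerm > 0)
        tab$pValue <- pv
    o <- order(-tab$partialR2, seq_len(n))   # ties keep grid order
    tab <- tab[o, , drop = FALSE]
    tab <- cbind(rank = seq_len(n), tab)
    rownames(tab) <- NULL
    tab
}

#' Coefficient of variation of absolute method differences
#'
#' Compares two run distance matrices over the same runs: the absolute
#' entrywise differences of the upper off-diagonal triangle are taken and
#' their coefficient of variation (standard deviation over mean, `n - 1`
#' denominator) is returned. Small values indicate a systematic (relevant)
#' difference between methods; a zero mean difference is undefined and
#' returns `NA` with a warning.
#'
#' @param d1,d2 [RunDistanceMatrix] objects (or symmetric matrices) with
#'   identical labels.
#' @return Non-negative CV, or `NA_real_`.
#' @export
compareMethodsCV <- function(d1, d2) {
    v1 <- .asDistValues(d1)
    v2 <- .asDistValues(d2)
    if (!identical(dim(v1), dim(v2)) ||
        !identical(rownames(v1), rownames(v2)))
        stop("distance matrices must cover the same runs")
    diffs <- abs(v1 - v2)[upper.tri(v1)]
    m <- mean(diffs)
    if (m == 0) {
        warning("mean absolute difference is 0; CV undefined")
        return(NA_real_)
    }
    stats::sd(diffs) / m
}
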