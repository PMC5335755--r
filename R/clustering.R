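#' @include AllClasses.R
NULL

#' Dendrogram: average-linkage clustering tree of runs
#'
#' Binary merge tree in `hclust` encoding: row `m` of `merge` gives the two
#' clusters fused at height `height[m]`, negative entries are leaves,
#' positive entries refer to earlier merges. Merge heights are
#' non-decreasing (UPGMA ultrametricity).
#'
#' @slot merge integer matrix `(N-1) x 2`.
#' @slot height numeric merge heights.
#' @slot labels leaf labels.
#' @slot order leaf ordering for plotting.
#' @exportClass Dendrogram
setClass("Dendrogram",
    representation(merge = "matrix", height = "numeric",
                   labels = "character", order = "integer"))

setValidity("Dendrogram", function(object) {
    msg <- character()
    n <- length(object@labels)
    if (!identical(dim(object@merge), c(n - 1L, 2L)))
        msg <- c(msg, "merge must be an (N-1) x 2 matrix")
    if (length(object@height) != n - 1L)
        msg <- c(msg, "need one height per merge")
    if (length(object@height) > 1L && any(diff(object@height) < -1e-12))
        msg <- c(msg, "merge heights must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' Average-linkage (UPGMA) tree of a run distance matrix
#'
#' Repeatedly fuses the pair of clusters with the smallest mean pairwise
#' distance between their members; the merge height is that mean. Ties are
#' broken deterministically in favour of the pair whose smallest member
#' labels sort lexicographically first.
#'
#' @param d a [RunDistanceMatrix] or symmetric labelled numeric matrix,
#'   `N >= 2`.
#' @return A [Dendrogram].
#' @examples
#' m <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tree <- averageLinkageTree(m)
#' toNewick(tree)
#' @export
averageLinkageTree <- function(d) {
    v <- if (is(d, "RunDistanceMatrix")) d@values else as.matrix(d)
    n <- nrow(v)
    if (n < 2L)
        stop("need at least two runs to cluster")
    if (!isTRUE(all.equal(v, t(v))))
        stop("distance matrix must be symmetric")
    labels <- rownames(v)
    if (is.null(labels))
        labels <- paste0("run", seq_len(n))
    ## active clusters: id (hclust code), size, minimal member label
    id <- -seq_len(n)
    size <- rep(1L, n)
    minLab <- labels
    D <- v
    diag(D) <- Inf
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (m in seq_len(n - 1L)) {
        nA <- length(id)
        best <- NULL
        bestKey <- NULL
        bestD <- Inf
        for (i in seq_len(nA - 1L)) {
            for (j in seq.int(i + 1L, nA)) {
                dij <- D[i, j]
                if (dij > bestD)
                    next
                key <- sort(c(minLab[i], minLab[j]))
                if (dij < bestD || is.null(bestKey) ||
                    key[1] < bestKey[1] ||
                    (key[1] == bestKey[1] && key[2] < bestKey[2])) {
                    bestD <- dij
                    best <- c(i, j)
                    bestKey <- key
                }
            }
        }
        i <- best[1]
        j <- best[2]
        ## first merge slot: cluster whose minimal label sorts first
        first <- if (minLab[i] <= minLab[j]) i else j
        second <- if (first == i) j else i
        merge[m, ] <- c(id[first], id[second])
        height[m] <- bestD
        ## average-linkage update to all remaining clusters
        others <- setdiff(seq_len(nA), c(i, j))
        newD <- (size[i] * D[i, others] + size[j] * D[j, others]) /
            (size[i] + size[j])
        D <- D[others, others, drop = FALSE]
        D <- rbind(cbind(D, newD), c(newD, Inf))
        newSize <- size[i] + size[j]
        newMin <- min(minLab[i], minLab[j])
        id <- c(id[others], m)
        size <- c(size[others], newSize)
        minLab <- c(minLab[others], newMin)
    }
    ## leaf order by traversal
    unfold <- function(node) {
        if (node < 0L) -node
        else c(unfold(merge[node, 1]), unfold(merge[node, 2]))
    }
    new("Dendrogram", merge = merge, height = height, labels = labels,
        order = as.integer(unfold(n - 1L)))
}

#' Convert a Dendrogram to stats::hclust
#'
#' @param x a [Dendrogram].
#' @param ... ignored.
#' @return An object of class `hclust`.
#' @export
asHclust <- function(x, ...) {
    stopifnot(is(x, "Dendrogram"))
    structure(list(merge = x@merge, height = x@height, order = x@order,
                   labels = x@labels, method = "average",
                   call = match.call(), dist.method = "disms2"),
              class = "hclust")
}

#' @exportS3Method stats::as.hclust
as.hclust.Dendrogram <- function(x, ...) asHclust(x)

#' Cophenetic distance matrix of a Dendrogram
#'
#' The cophenetic distance of two leaves is the merge height of their lowest
#' common ancestor.
#'
#' @param x a [Dendrogram].
#' @return A symmetric labelled matrix.
#' @export
copheneticMatrix <- function(x) {
    as.matrix(stats::cophenetic(asHclust(x)))
}

## minimal leaf label of a merge-tree node, for deterministic child ordering
.minLeafLabel <- function(tree, node) {
    if (node < 0L)
        return(tree@labels[-node])
    min(.minLeafLabel(tree, tree@merge[node, 1]),
        .minLeafLabel(tree, tree@merge[node, 2]))
}

#' Serialize a Dendrogram to Newick
#'
#' Branch lengths halve the merge heights so that the tree is ultrametric
#' with leaf depth equal to half the root height — the path length between
#' two leaves then equals their cophenetic distance. Children are ordered by
#' their lexicographically smallest leaf label.
#'
#' @param tree a [Dendrogram].
#' @param digits significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
toNewick <- function(tree, digits = 10) {
    stopifnot(is(tree, "Dendrogram"))
    fmt <- function(x) sprintf("%.*g", digits, x)
    build <- function(node, parentHeight) {
        if (node < 0L) {
            h <- 0
            lab <- tree@labels[-node]
        } else {
            h <- tree@height[node]
            kids <- tree@merge[node, ]
            kids <- kids[order(vapply(kids, .minLeafLabel, "",
                                      tree = tree))]
            lab <- paste0("(",
                paste(vapply(kids, build, "", parentHeight = h),
                      collapse = ","), ")")
        }
        paste0(lab, ":", fmt((parentHeight - h) / 2))
    }
    root <- nrow(tree@merge)
    h <- tree@height[root]
    kids <- tree@merge[root, ]
    kids <- kids[order(vapply(kids, .minLeafLabel, "", tree = tree))]
    paste0("(", paste(vapply(kids, build, "", parentHeight = h),
                      collapse = ","), ");")
}

#' Write a Newick tree file
#'
#' @param tree a [Dendrogram].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
    writeLines(toNewick(tree), path)
    invisible(path)
}
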