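#' Mean silhouette coefficient of a labelled embedding
#'
#' Average over cells of s(i) = (b(i) - a(i)) / max(a(i), b(i)), where a(i)
#' is the mean Euclidean distance of cell i to its own group and b(i) the
#' mean distance to the nearest other group. Computed exactly (all pairwise
#' distances) up to `maxCells` cells; larger inputs are subsampled with the
#' given seed.
#'
#' @param embedding cells x dims numeric matrix (e.g. module activities)
#' @param labels per-cell category vector (>= 2 categories, each with >= 2
#'   cells)
#' @param maxCells exact-computation ceiling (default 10000)
#' @param seed seed for subsampling beyond `maxCells`
#' @return scalar in [-1, 1]
#' @export
silhouetteScore <- function(embedding, labels, maxCells = 10000L,
                            seed = 0L) {
    embedding <- as.matrix(embedding)
    labels <- as.character(labels)
    if (length(labels) != nrow(embedding))
        stop("labels must have one entry per row of the embedding")
    tab <- table(labels)
    if (length(tab) < 2L) stop("need at least 2 categories")
    if (any(tab < 2L))
        stop("singleton category: ", names(tab)[tab < 2L][1L])
    n <- nrow(embedding)
    if (n > maxCells) {
        keep <- withr::with_seed(as.integer(seed),
                                 sort(sample.int(n, maxCells)))
        embedding <- embedding[keep, , drop = FALSE]
        labels <- labels[keep]
        tab <- table(labels)
        if (length(tab) < 2L || any(tab < 2L))
            stop("subsample lost a category; raise maxCells")
    }
    sil <- cluster::silhouette(as.integer(factor(labels)), dist(embedding))
    mean(sil[, "sil_width"])
}

#' R-squared between mean expression profiles
#'
#' Collapses each matrix to its per-gene mean over cells and returns the
#' squared Pearson correlation of the two gene-length vectors — the
#' reconstruction-quality summary used to compare real and decoded data.
#' Invariant to affine rescaling of either profile and symmetric in its
#' arguments.
#'
#' @param real cells x genes matrix
#' @param recon cells x genes matrix over the same genes in the same order
#' @return scalar in [0, 1]
#' @export
meanExpressionR2 <- function(real, recon) {
    real <- as.matrix(real); recon <- as.matrix(recon)
    if (ncol(real) != ncol(recon))
        stop("matrices must cover the same genes in the same order")
    if (!is.null(colnames(real)) && !is.null(colnames(recon)) &&
        !identical(colnames(real), colnames(recon)))
        stop("gene name order differs between the two matrices")
    m1 <- colMeans(real)
    m2 <- colMeans(recon)
    if (sd(m1) == 0 || sd(m2) == 0)
        stop("zero variance in a mean-expression vector; ",
             "R-squared is undefined")
    cor(m1, m2)^2
}

#' Overlap of two top-k rankings
#'
#' Proportion of shared elements among the top k entries of two ordered
#' rankings: |top-k(a) n top-k(b)| / k.
#'
#' @param rankingA,rankingB character vectors ordered best-first, without
#'   duplicates
#' @param k depth of the comparison (default 50)
#' @return scalar in [0, 1]
#' @export
topKOverlap <- function(rankingA, rankingB, k = 50L) {
    rankingA <- as.character(rankingA)
    rankingB <- as.character(rankingB)
    if (anyDuplicated(rankingA) || anyDuplicated(rankingB))
        stop("rankings must not contain duplicate names")
    if (k > min(length(rankingA), length(rankingB)))
        stop("k exceeds the length of a ranking")
    length(intersect(head(rankingA, k), head(rankingB, k))) / k
}
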