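#' Monte-Carlo Bayes factor between two sets of latent posteriors
#'
#' Core of the differential-activity test, operating directly on per-cell
#' posterior means and standard deviations for the gene-module nodes. For
#' each module it samples `nPairs` cell pairs (with replacement, uniformly
#' within each group), draws `nMc` reparametrized samples from each cell's
#' posterior, and estimates p(H0) — the posterior probability that group A's
#' activity exceeds group B's — as the fraction of draws with `z_a > z_b`
#' (ties count one half, keeping the A/B symmetry exact). The log-Bayes
#' factor is the natural-log posterior odds `K = ln(p / (1 - p))`, with p
#' clamped to `[eps, 1 - eps]`, `eps = 1 / (nPairs * nMc)`, so K is always
#' finite. MD is the absolute difference of group-mean posterior means.
#'
#' @param muA,sdA cellsA x modules matrices of posterior means/standard
#'   deviations for group A
#' @param muB,sdB matching matrices for group B
#' @param nPairs number of sampled cell pairs (default 5000)
#' @param nMc Monte-Carlo draws per cell of a pair (default 10)
#' @param seed integer seed
#' @return `data.frame` with columns `gmv`, `p_h0`, `K`, `MD`
#' @export
bayesFactorLatent <- function(muA, sdA, muB, sdB, nPairs = 5000L,
                              nMc = 10L, seed = 0L) {
    stopifnot(is.matrix(muA), is.matrix(muB),
              identical(dim(muA), dim(sdA)),
              identical(dim(muB), dim(sdB)),
              ncol(muA) == ncol(muB), nPairs >= 1L, nMc >= 1L)
    K <- ncol(muA)
    nms <- colnames(muA) %||% paste0("gmv_", seq_len(K))
    res <- withr::with_seed(as.integer(seed), {
        ia <- sample.int(nrow(muA), nPairs, replace = TRUE)
        ib <- sample.int(nrow(muB), nPairs, replace = TRUE)
        p <- numeric(K)
        for (k in seq_len(K)) {
            za <- muA[ia, k] + sdA[ia, k] *
                matrix(rnorm(nPairs * nMc), nPairs, nMc)
            zb <- muB[ib, k] + sdB[ib, k] *
                matrix(rnorm(nPairs * nMc), nPairs, nMc)
            p[k] <- mean((za > zb) + 0.5 * (za == zb))
        }
        p
    })
    epsClamp <- 1 / (nPairs * nMc)
    p <- pmin(pmax(res, epsClamp), 1 - epsClamp)
    data.frame(gmv = nms, p_h0 = p, K = log(p / (1 - p)),
               MD = abs(colMeans(muA) - colMeans(muB)))
}

.resolveGroup <- function(mask, n, cellNames, what) {
    if (is.logical(mask)) {
        if (length(mask) != n)
            stop(what, " logical mask length must equal cell count")
        which(mask)
    } else if (is.character(mask)) {
        idx <- match(mask, cellNames)
        if (anyNA(idx)) stop(what, " contains unknown cell identifiers")
        idx
    } else {
        idx <- as.integer(mask)
        if (any(idx < 1L | idx > n)) stop(what, " indices out of range")
        idx
    }
}

#' Differential gene-module activity between two cell groups
#'
#' Bayesian hypothesis test of whether each gene-module node is activated at
#' a higher level in group A than in group B, via the Monte-Carlo log-Bayes
#' factor over the encoder posteriors (see [bayesFactorLatent()]). By the
#' usual convention, |K| > 3 (posterior odds about 20:1) is called
#' significant; an optional floor on MD, the absolute difference of
#' group-mean activities, filters weak effects.
#'
#' @param model a trained [VegaModel-class]
#' @param data a `SummarizedExperiment`
#' @param groupA,groupB disjoint cell selections: logical masks, integer
#'   indices, or cell identifiers
#' @param nPairs sampled cell pairs (default 5000)
#' @param nMc Monte-Carlo draws per cell (default 10)
#' @param kThreshold significance threshold on |K| (default 3)
#' @param mdThreshold significance floor on MD (default 0 = off)
#' @param seed integer seed
#' @return an `S4Vectors::DataFrame` with one row per gene module and
#'   columns `gmv`, `p_h0`, `K`, `MD`, `significant`; test metadata (group
#'   sizes, nPairs, nMc, seed, thresholds) in `metadata()`
#' @export
differentialActivity <- function(model, data, groupA, groupB,
                                 nPairs = 5000L, nMc = 10L,
                                 kThreshold = 3, mdThreshold = 0,
                                 seed = 0L) {
    stopifnot(is(model, "VegaModel"))
    X <- .alignedCellMatrix(model, data, strict = FALSE)
    cells <- rownames(X)
    ia <- .resolveGroup(groupA, nrow(X), cells, "groupA")
    ib <- .resolveGroup(groupB, nrow(X), cells, "groupB")
    if (length(ia) == 0L) stop("groupA is empty")
    if (length(ib) == 0L) stop("groupB is empty")
    if (length(intersect(ia, ib)) > 0L)
        stop("groupA and groupB overlap (", length(intersect(ia, ib)),
             " shared cells)")
    covariates <- if (is(data, "SummarizedExperiment") &&
                      model@layout@nCovariate > 0L)
        .covariateCodes(model, data) else NULL
    post <- encode(model, X, covariates = covariates)
    idx <- which(model@layout@nodeKinds == "gmv")
    mu <- post@mu[, idx, drop = FALSE]
    sd_ <- post@sigma[, idx, drop = FALSE]
    bf <- bayesFactorLatent(mu[ia, , drop = FALSE], sd_[ia, , drop = FALSE],
                            mu[ib, , drop = FALSE], sd_[ib, , drop = FALSE],
                            nPairs = nPairs, nMc = nMc, seed = seed)
    out <- S4Vectors::DataFrame(bf)
    out$significant <- abs(out$K) > kThreshold & out$MD >= mdThreshold
    S4Vectors::metadata(out) <- list(
        nA = length(ia), nB = length(ib), nPairs = as.integer(nPairs),
        nMc = as.integer(nMc), seed = as.integer(seed),
        kThreshold = kThreshold, mdThreshold = mdThreshold)
    out
}

#' One-vs-rest differential module activity
#'
#' Runs [differentialActivity()] for each category of a per-cell label
#' against all remaining cells — the module-level analogue of one-vs-rest
#' differential expression. Per-category seeds are derived deterministically
#' from `seed` so each comparison is reproducible in isolation.
#'
#' @param model a trained [VegaModel-class]
#' @param data a `SummarizedExperiment`
#' @param labels per-cell category vector, or the name of a `colData` column
#' @param ... passed on to [differentialActivity()]
#' @param seed base seed
#' @return named list of `DataFrame`s, one per category
#' @export
oneVsRest <- function(model, data, labels, ..., seed = 0L) {
    if (is.character(labels) && length(labels) == 1L) {
        cd <- SummarizedExperiment::colData(data)
        if (!labels %in% colnames(cd))
            stop("colData column not found: ", labels)
        labels <- as.character(cd[[labels]])
    }
    labels <- as.character(labels)
    lev <- unique(labels)
    if (length(lev) < 2L) stop("one-vs-rest needs at least 2 categories")
    single <- lev[table(factor(labels, lev)) == 1L]
    if (length(single) > 0L)
        warning("singleton category(ies): ",
                paste(single, collapse = ", "),
                "; the test still runs but is unstable")
    res <- lapply(seq_along(lev), function(i) {
        differentialActivity(model, data,
                             groupA = labels == lev[i],
                             groupB = labels != lev[i], ...,
                             seed = (as.integer(seed) + 7919L * i) %%
                                 .Machine$integer.max)
    })
    names(res) <- lev
    res
}

#' Rank modules and call significance
#'
#' Orders a differential result by |K| descending (ties broken by MD, then
#' module name) and sets the significance flag at the given thresholds.
#'
#' @param result a `DataFrame`/`data.frame` from [differentialActivity()]
#' @param kThreshold threshold on |K| (default 3)
#' @param mdThreshold floor on MD (default 0)
#' @return the reordered table with an updated `significant` column
#' @export
rankAndCall <- function(result, kThreshold = 3, mdThreshold = 0) {
    stopifnot(all(c("gmv", "K", "MD") %in% colnames(result)))
    ord <- order(-abs(result$K), -result$MD, result$gmv)
    out <- result[ord, ]
    out$significant <- abs(out$K) > kThreshold & out$MD >= mdThreshold
    out
}

#' Write a differential result as TSV
#'
#' @param result table from [differentialActivity()] or [rankAndCall()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDifferential <- function(result, path) {
    write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
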