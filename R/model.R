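#' Construct a gene-module VAE
#'
#' Builds an untrained model from a decoder mask: a multilayer nonlinear
#' encoder mapping expression to the mean and log-variance of a diagonal
#' Gaussian posterior over the latent nodes, and a single masked linear
#' decoder whose weights are wired to the gene modules (zero wherever the
#' mask is zero) and constrained to be nonnegative so that a latent value
#' reads as the *activity* of its module. Fully-connected and covariate
#' columns of the mask are all-ones.
#'
#' Initialization: hidden layers use He-normal weights (suited to the ReLU
#' activations), posterior heads use scaled-normal weights, and the decoder
#' is drawn uniform then clamped to the mask and to nonnegativity, so at
#' least the masked fraction of decoder entries is exactly zero from the
#' start. All draws flow from `seed`; two calls with the same seed yield
#' bitwise-identical parameters.
#'
#' @param mask either the list returned by [buildMask()] or a genes x latent
#'   binary matrix (then `layout` is required)
#' @param layout a [LatentLayout-class]; ignored when `mask` is a
#'   [buildMask()] result
#' @param genes training gene order; defaults to `rownames(mask)`
#' @param nHidden width of each encoder hidden layer (default 800)
#' @param nLayers number of encoder hidden layers (default 2)
#' @param dropoutRate encoder dropout rate during training (default 0.2)
#' @param latentDropout dropout rate on the sampled latent vector during
#'   training (default 0.3); preserves redundancy between overlapping
#'   modules
#' @param decoderBias add one free (unmasked) offset per gene? default TRUE
#' @param covariateColumn name of the `colData` column holding the
#'   conditioning covariate (default `"batch"`); only used when the layout
#'   has covariate nodes
#' @param seed integer seed for parameter initialization
#' @return a [VegaModel-class]
#' @examples
#' gmc <- GeneModuleCollection(list(M1 = c("G1", "G2"), M2 = c("G2", "G3")))
#' bm <- buildMask(gmc, paste0("G", 1:4), nFC = 1, minGenes = 2)
#' m <- vegaModel(bm, nHidden = 8, seed = 1)
#' m
#' @export
vegaModel <- function(mask, layout = NULL, genes = NULL, nHidden = 800L,
                      nLayers = 2L, dropoutRate = 0.2, latentDropout = 0.3,
                      decoderBias = TRUE, covariateColumn = "batch",
                      seed = 0L) {
    if (is.list(mask) && !is.matrix(mask)) {
        layout <- mask$layout
        mask <- mask$mask
    }
    if (is.null(layout)) stop("layout is required when mask is a bare matrix")
    stopifnot(is(layout, "LatentLayout"), is.matrix(mask))
    L <- layout@nGMV + layout@nFC + layout@nCovariate
    if (ncol(mask) != L)
        stop("mask has ", ncol(mask), " columns but layout describes ",
             L, " latent nodes")
    if (is.null(genes)) genes <- rownames(mask)
    if (is.null(genes)) stop("gene names missing: pass genes= or a named mask")
    if (length(genes) != nrow(mask))
        stop("genes length must equal mask row count")
    storage.mode(mask) <- "double"
    g <- nrow(mask)
    nHidden <- as.integer(nHidden); nLayers <- as.integer(nLayers)
    stopifnot(nHidden >= 1L, nLayers >= 1L,
              dropoutRate >= 0, dropoutRate < 1,
              latentDropout >= 0, latentDropout < 1)

    params <- withr::with_seed(as.integer(seed), {
        p <- list(encW = vector("list", nLayers),
                  encB = vector("list", nLayers))
        fanIn <- g
        for (l in seq_len(nLayers)) {
            p$encW[[l]] <- matrix(rnorm(fanIn * nHidden, sd = sqrt(2 / fanIn)),
                                  fanIn, nHidden)
            p$encB[[l]] <- numeric(nHidden)
            fanIn <- nHidden
        }
        p$muW <- matrix(rnorm(nHidden * L, sd = sqrt(1 / nHidden)),
                        nHidden, L)
        p$muB <- numeric(L)
        p$lvW <- matrix(rnorm(nHidden * L, sd = sqrt(1 / nHidden)),
                        nHidden, L)
        p$lvB <- numeric(L)
        a <- 1 / sqrt(max(L, 1L))
        D <- matrix(runif(g * L, min = -a, max = a), g, L)
        p$decoderW <- pmax(D, 0) * mask
        p$decoderB <- numeric(g)
        p
    })
    dimnames(params$decoderW) <- dimnames(mask)

    new("VegaModel", params = params, mask = mask, layout = layout,
        genes = as.character(genes),
        config = list(nHidden = nHidden, nLayers = nLayers,
                      dropoutRate = dropoutRate,
                      latentDropout = latentDropout,
                      decoderBias = decoderBias,
                      covariateColumn = covariateColumn,
                      initSeed = as.integer(seed)),
        trained = FALSE)
}

setMethod("show", "VegaModel", function(object) {
    lay <- object@layout
    cat("VegaModel:", length(object@genes), "genes ->",
        lay@nGMV, "GMV +", lay@nFC, "FC +", lay@nCovariate,
        "covariate latent nodes\n")
    cat("  encoder:", object@config$nLayers, "x", object@config$nHidden,
        "hidden units; decoder:",
        if (object@config$decoderBias) "masked linear + bias"
        else "masked linear",
        "\n  trained:", object@trained, "\n")
})

#' @rdname latentNames
#' @export
setMethod("latentNames", "VegaModel", function(x) x@layout@latentNames)

#' Number of gene-module latent nodes
#' @param model a [VegaModel-class]
#' @return integer
#' @export
nGMV <- function(model) model@layout@nGMV

.LOGVAR_CLAMP <- 8

# Encoder forward pass. X: cells x genes. Returns activations needed for
# backprop. dropMasks/latDrop are NULL in evaluation mode (no dropout).
.encForward <- function(params, X, dropMasks = NULL) {
    nL <- length(params$encW)
    A <- vector("list", nL + 1L)
    Zpre <- vector("list", nL)
    A[[1L]] <- X
    for (l in seq_len(nL)) {
        Zl <- sweep(A[[l]] %*% params$encW[[l]], 2L, params$encB[[l]], "+")
        H <- pmax(Zl, 0)
        if (!is.null(dropMasks)) H <- H * dropMasks[[l]]
        Zpre[[l]] <- Zl
        A[[l + 1L]] <- H
    }
    H <- A[[nL + 1L]]
    mu <- sweep(H %*% params$muW, 2L, params$muB, "+")
    lvRaw <- sweep(H %*% params$lvW, 2L, params$lvB, "+")
    lv <- pmax(pmin(lvRaw, .LOGVAR_CLAMP), -.LOGVAR_CLAMP)
    list(A = A, Zpre = Zpre, mu = mu, logvar = lv,
         lvMask = (lvRaw > -.LOGVAR_CLAMP & lvRaw < .LOGVAR_CLAMP))
}

# one-hot matrix for covariate codes (n x nLevels)
.oneHot <- function(codes, nLevels) {
    O <- matrix(0, length(codes), nLevels)
    O[cbind(seq_along(codes), codes)] <- 1
    O
}

#' Encode cells into the latent posterior
#'
#' Runs the encoder in evaluation mode (dropout disabled) and returns the
#' per-cell diagonal Gaussian posterior q(z | x). Covariate nodes are set
#' deterministically from each cell's covariate label (posterior mean equal
#' to the one-hot code, vanishing standard deviation), since the decoder is
#' conditioned on the label rather than on an inferred quantity.
#'
#' @param model a [VegaModel-class]
#' @param data a `SummarizedExperiment` whose genes match the training gene
#'   order, or a cells x genes matrix in training gene order
#' @param covariates optional integer codes (1-based into the layout's
#'   `covariateLevels`) when `data` is a bare matrix
#' @param ... unused
#' @return a [LatentPosterior-class]
#' @rdname encode
#' @export
setMethod("encode", "VegaModel", function(model, data, covariates = NULL,
                                          ...) {
    X <- .alignedCellMatrix(model, data, strict = TRUE)
    if (is(data, "SummarizedExperiment") && model@layout@nCovariate > 0L)
        covariates <- .covariateCodes(model, data)
    fw <- .encForward(model@params, X)
    mu <- fw$mu
    sigma <- exp(0.5 * fw$logvar)
    lay <- model@layout
    if (lay@nCovariate > 0L) {
        idx <- which(lay@nodeKinds == "covariate")
        if (is.null(covariates))
            stop("model carries covariate nodes but no covariate codes ",
                 "were provided")
        mu[, idx] <- .oneHot(covariates, lay@nCovariate)
        sigma[, idx] <- 1e-6
    }
    dimnames(mu) <- list(rownames(X), lay@latentNames)
    dimnames(sigma) <- dimnames(mu)
    new("LatentPosterior", mu = mu, sigma = sigma,
        latentNames = lay@latentNames, nodeKinds = lay@nodeKinds)
})

# Align data to the model's training gene order. strict=TRUE errors on any
# mismatch (encode contract); strict=FALSE zero-fills missing genes and
# drops extras, with a 50% overlap floor (projection contract).
.alignedCellMatrix <- function(model, data, strict = TRUE) {
    if (is(data, "SummarizedExperiment")) {
        X <- .cellMatrix(data)
    } else {
        X <- as.matrix(data)
        if (is.null(colnames(X))) {
            if (ncol(X) != length(model@genes))
                stop("expression matrix has ", ncol(X),
                     " genes; model expects ", length(model@genes))
            colnames(X) <- model@genes
        }
    }
    gg <- model@genes
    if (identical(colnames(X), gg)) return(X)
    common <- intersect(gg, colnames(X))
    if (strict) {
        if (length(common) == length(gg) && ncol(X) == length(gg))
            return(X[, gg, drop = FALSE])  # same genes, different order
        stop("gene mismatch: model expects ", length(gg),
             " training genes; provide the same gene set ",
             "(projection with reconciliation: gmvActivities/",
             "reconstructExpression)")
    }
    if (length(common) < 0.5 * length(gg))
        stop("only ", length(common), " of ", length(gg), " training genes ",
             "present (<50%); projection would be meaningless")
    out <- matrix(0, nrow(X), length(gg),
                  dimnames = list(rownames(X), gg))
    out[, common] <- X[, common]
    nMissing <- length(gg) - length(common)
    if (nMissing > 0L)
        warning(nMissing, " training gene(s) absent from the data; ",
                "zero-filled")
    extra <- setdiff(colnames(X), gg)
    if (length(extra) > 0L)
        warning(length(extra), " gene(s) not seen at training dropped")
    out
}

#' Draw a latent sample via the reparametrization trick
#'
#' Returns z = mu + sigma * eps with eps drawn from a standard normal,
#' reproducibly for a given seed.
#'
#' @param posterior a [LatentPosterior-class]
#' @param seed integer seed
#' @return cells x latent numeric matrix
#' @export
sampleLatent <- function(posterior, seed = 0L) {
    stopifnot(is(posterior, "LatentPosterior"))
    eps <- withr::with_seed(as.integer(seed),
        matrix(rnorm(length(posterior@mu)), nrow(posterior@mu)))
    z <- posterior@mu + posterior@sigma * eps
    dimnames(z) <- dimnames(posterior@mu)
    z
}

#' Decode latent values into expression space
#'
#' Applies the masked linear decoder: `X_hat = Z %*% t(W) + b`. A gene
#' outside module j receives zero contribution from latent node j, and
#' because the weights are nonnegative, increasing a module's activity never
#' decreases any gene's reconstruction.
#'
#' @param model a [VegaModel-class]
#' @param Z cells x latent numeric matrix
#' @param ... unused
#' @return cells x genes reconstruction
#' @rdname decode
#' @export
setMethod("decode", "VegaModel", function(model, Z, ...) {
    Z <- as.matrix(Z)
    if (ncol(Z) != ncol(model@mask))
        stop("Z has ", ncol(Z), " columns; model latent dimension is ",
             ncol(model@mask))
    out <- Z %*% t(model@params$decoderW)
    if (isTRUE(model@config$decoderBias))
        out <- sweep(out, 2L, model@params$decoderB, "+")
    colnames(out) <- model@genes
    out
})

#' Re-impose the decoder constraints
#'
#' Sets masked decoder entries to exactly zero and clamps negative unmasked
#' entries to zero. Idempotent; called automatically after every optimizer
#' step, and exposed for audits.
#'
#' @param model a [VegaModel-class]
#' @return the constrained model
#' @export
constrainDecoder <- function(model) {
    stopifnot(is(model, "VegaModel"))
    model@params$decoderW <- pmax(model@params$decoderW, 0) * model@mask
    model
}
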