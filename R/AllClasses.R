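#' @import methods
#' @importFrom stats rnorm runif setNames cor dist sd quantile
#' @importFrom utils head write.table read.csv read.table packageVersion
#' @importFrom tools md5sum file_path_sans_ext
NULL

#' GeneModuleCollection: ordered, named gene sets
#'
#' An ordered collection of named gene modules (pathways, regulons, marker
#' sets). Each module is a set of gene identifiers; iteration order is the
#' order of the source file, module names are unique, and every module holds
#' at least one gene.
#'
#' @slot modules named list of character vectors (the gene sets, deduplicated)
#' @slot descriptions character vector parallel to `modules`
#' @export
setClass("GeneModuleCollection",
    representation(modules = "list", descriptions = "character"),
    prototype(modules = structure(list(), names = character(0)),
              descriptions = character(0)))

setValidity("GeneModuleCollection", function(object) {
    nm <- names(object@modules)
    if (length(object@modules) > 0L && (is.null(nm) || any(nm == "")))
        return("all modules must be named")
    if (anyDuplicated(nm))
        return(sprintf("duplicate module name(s): %s",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(object@descriptions) != length(object@modules))
        return("descriptions must be parallel to modules")
    if (any(vapply(object@modules, length, 1L) < 1L))
        return("every module must contain at least one gene")
    if (!all(vapply(object@modules, is.character, TRUE)))
        return("modules must be character vectors of gene identifiers")
    TRUE
})

#' LatentLayout: bookkeeping for the latent space
#'
#' Records how latent nodes split into gene-module variables (GMVs), extra
#' fully-connected (FC) nodes, and covariate nodes (one per level of the
#' conditioning covariate, e.g. batch). More than 16 FC nodes triggers a
#' warning at construction, reflecting the recommendation to keep the number
#' of free nodes small so they do not absorb signal that belongs to the GMVs.
#'
#' @slot nGMV integer, number of gene-module nodes
#' @slot nFC integer, number of fully-connected nodes
#' @slot nCovariate integer, number of covariate (one-hot) nodes
#' @slot covariateLevels character, ordered levels of the covariate
#' @slot latentNames character, ordered labels for all latent nodes
#' @slot nodeKinds character in {"gmv","fc","covariate"}, parallel to
#'   `latentNames`
#' @export
setClass("LatentLayout",
    representation(nGMV = "integer", nFC = "integer", nCovariate = "integer",
                   covariateLevels = "character", latentNames = "character",
                   nodeKinds = "character"))

setValidity("LatentLayout", function(object) {
    total <- object@nGMV + object@nFC + object@nCovariate
    if (length(object@latentNames) != total)
        return("latentNames length must equal nGMV + nFC + nCovariate")
    if (length(object@nodeKinds) != total)
        return("nodeKinds length must equal total latent dimension")
    if (!all(object@nodeKinds %in% c("gmv", "fc", "covariate")))
        return("nodeKinds must be 'gmv', 'fc' or 'covariate'")
    if (sum(object@nodeKinds == "gmv") != object@nGMV ||
        sum(object@nodeKinds == "fc") != object@nFC ||
        sum(object@nodeKinds == "covariate") != object@nCovariate)
        return("nodeKinds tallies disagree with nGMV/nFC/nCovariate")
    if (object@nCovariate > 0L &&
        length(object@covariateLevels) != object@nCovariate)
        return("covariateLevels must have one entry per covariate node")
    if (anyDuplicated(object@latentNames))
        return("latent node names must be unique")
    TRUE
})

#' VegaModel: masked-decoder variational autoencoder
#'
#' Holds the encoder parameters (a multilayer perceptron mapping expression
#' to the mean and log-variance of the latent Gaussian posterior), the
#' decoder (a single linear layer whose weight matrix is constrained to the
#' binary gene-membership mask and to nonnegative values), the mask itself,
#' and the latent layout. Construct with [vegaModel()]; do not fill slots by
#' hand.
#'
#' @slot params list of numeric matrices/vectors (encoder layers, posterior
#'   heads, decoder weights and bias)
#' @slot mask genes x latent binary matrix
#' @slot layout a [LatentLayout-class]
#' @slot genes character, training gene order
#' @slot config list of architecture hyperparameters
#' @slot trained logical flag
#' @export
setClass("VegaModel",
    representation(params = "list", mask = "matrix", layout = "LatentLayout",
                   genes = "character", config = "list", trained = "logical"))

setValidity("VegaModel", function(object) {
    D <- object@params$decoderW
    if (!is.null(D)) {
        if (!identical(dim(D), dim(object@mask)))
            return("decoder weight matrix must match mask dimensions")
        if (any(D[object@mask == 0] != 0))
            return("masked decoder weights must be exactly zero")
        if (min(D) < 0)
            return("decoder weights must be nonnegative")
    }
    if (length(object@genes) != nrow(object@mask))
        return("gene list length must equal mask row count")
    TRUE
})

#' LatentPosterior: per-cell Gaussian posterior over latent nodes
#'
#' The variational posterior q(z | x) returned by [encode()]: a diagonal
#' Gaussian per cell, stored as a cells x latent matrix of means and a
#' matching matrix of strictly positive standard deviations.
#'
#' @slot mu cells x latent numeric matrix of posterior means
#' @slot sigma cells x latent numeric matrix of posterior standard deviations
#' @slot latentNames character, latent node labels (column names)
#' @slot nodeKinds character, per-node tags as in [LatentLayout-class]
#' @export
setClass("LatentPosterior",
    representation(mu = "matrix", sigma = "matrix",
                   latentNames = "character", nodeKinds = "character"))

setValidity("LatentPosterior", function(object) {
    if (!identical(dim(object@mu), dim(object@sigma)))
        return("mu and sigma must have identical dimensions")
    if (any(!is.finite(object@mu)) || any(!is.finite(object@sigma)))
        return("posterior parameters must be finite")
    if (any(object@sigma <= 0))
        return("sigma must be strictly positive")
    if (length(object@latentNames) != ncol(object@mu))
        return("latentNames must label the columns of mu")
    TRUE
})
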