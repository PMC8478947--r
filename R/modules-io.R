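#' Construct a GeneModuleCollection
#'
#' @param modules named list of character vectors of gene identifiers.
#'   Genes are deduplicated (first occurrence kept); order of modules is
#'   preserved.
#' @param descriptions optional character vector of free-text descriptions,
#'   recycled from "" if missing.
#' @return a [GeneModuleCollection-class]
#' @examples
#' gmc <- GeneModuleCollection(list(SETA = c("G1", "G2"), SETB = c("G2")))
#' moduleSizes(gmc)
#' @export
GeneModuleCollection <- function(modules, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- rep("", length(modules))
    modules <- lapply(modules, function(g) unique(as.character(g)))
    new("GeneModuleCollection", modules = modules,
        descriptions = as.character(descriptions))
}

#' Read gene modules from a GMT file
#'
#' Parses the tab-separated GMT convention used by MSigDB and Reactome
#' exports: one gene set per line, fields `name`, `description`, then one
#' gene identifier per remaining field. Genes are deduplicated within a set;
#' file order is preserved.
#'
#' @param path path to a GMT file
#' @param toupper if `TRUE`, uppercase all gene identifiers (helps reconcile
#'   symbol-case conventions between annotation databases and datasets)
#' @return a [GeneModuleCollection-class]
#' @export
readGMT <- function(path, toupper = FALSE) {
    if (!file.exists(path))
        stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(GeneModuleCollection(structure(list(), names = character(0))))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(fields, length, 1L)
    if (any(nf < 3L))
        stop("malformed GMT line ", which(nf < 3L)[1L],
             ": expected at least 3 tab-separated fields (name, ",
             "description, genes...)")
    nms <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(nms))
        stop("duplicate module name in GMT file: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    desc <- vapply(fields, `[[`, "", 2L)
    genes <- lapply(fields, function(f) {
        g <- f[-(1:2)]
        g <- g[nzchar(g)]
        if (toupper) g <- base::toupper(g)
        unique(g)
    })
    names(genes) <- nms
    GeneModuleCollection(genes, desc)
}

#' Write a GeneModuleCollection as GMT
#'
#' @param x a [GeneModuleCollection-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "GeneModuleCollection"))
    lines <- vapply(seq_along(x@modules), function(i) {
        paste(c(names(x@modules)[i], x@descriptions[i], x@modules[[i]]),
              collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read gene modules from a regulator-target edge list
#'
#' Consumes a two-column table (regulator, target), e.g. an ARACNe-style
#' network export, and builds one module per regulator whose genes are that
#' regulator's targets. Regulator order follows first appearance in the
#' file. Self-edges (a regulator listed as its own target) are retained as
#' given.
#'
#' @param path path to a TSV/whitespace-delimited two-column table
#' @param header logical; does the file carry a header row?
#' @param sep field separator, default tab
#' @return a [GeneModuleCollection-class]
#' @export
readRegulonTable <- function(path, header = FALSE, sep = "\t") {
    if (!file.exists(path))
        stop("regulon table not found: ", path)
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L || !nzchar(trimws(first)))
        return(GeneModuleCollection(structure(list(), names = character(0))))
    tab <- read.table(path, header = header, sep = sep,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
    if (ncol(tab) < 2L)
        stop("regulon table must have at least 2 columns ",
             "(regulator, target); found ", ncol(tab))
    reg <- as.character(tab[[1L]])
    tgt <- as.character(tab[[2L]])
    mods <- split(tgt, factor(reg, levels = unique(reg)))
    GeneModuleCollection(as.list(mods))
}

#' @describeIn GeneModuleCollection number of modules
#' @param x a GeneModuleCollection
#' @export
setMethod("length", "GeneModuleCollection", function(x) length(x@modules))

#' @describeIn GeneModuleCollection module names, in file order
#' @export
setMethod("names", "GeneModuleCollection", function(x) names(x@modules))

#' @rdname moduleNames
#' @param x a GeneModuleCollection
#' @export
setMethod("moduleNames", "GeneModuleCollection",
          function(x) names(x@modules))

#' Sizes of the gene modules
#'
#' @param x a [GeneModuleCollection-class]
#' @return named integer vector of module sizes
#' @rdname moduleSizes
#' @export
setMethod("moduleSizes", "GeneModuleCollection", function(x)
    vapply(x@modules, length, 1L))

#' @describeIn GeneModuleCollection extract one module's gene set
#' @param i index or module name
#' @export
setMethod("[[", "GeneModuleCollection", function(x, i) x@modules[[i]])

#' @describeIn GeneModuleCollection subset to a sub-collection
#' @param j,drop,... ignored
#' @export
setMethod("[", "GeneModuleCollection", function(x, i, j, ..., drop = FALSE)
    GeneModuleCollection(x@modules[i], x@descriptions[i]))

setMethod("show", "GeneModuleCollection", function(object) {
    cat("GeneModuleCollection with", length(object@modules), "modules\n")
    n <- min(5L, length(object@modules))
    if (n > 0L) {
        sz <- moduleSizes(object)
        for (i in seq_len(n))
            cat(sprintf("  %s (%d genes)\n", names(object@modules)[i], sz[i]))
        if (length(object@modules) > n) cat("  ...\n")
    }
})

#' Build the binary decoder mask from gene modules
#'
#' Intersects each module with the dataset's gene universe and builds the
#' genes x latent binary matrix wiring the masked linear decoder: entry
#' (i, j) is 1 exactly when gene i belongs to module j. Modules whose
#' intersection with the gene universe falls below `minGenes` are dropped
#' with a warning. Extra fully-connected nodes and covariate nodes are
#' appended, in that order, as all-ones columns (connected to every gene).
#'
#' @param collection a [GeneModuleCollection-class]
#' @param genes ordered character vector, the dataset's gene universe
#' @param nFC number of extra fully-connected latent nodes (default 0);
#'   values above 16 trigger a warning since large numbers of free nodes
#'   can siphon signal away from the module nodes
#' @param covariateLevels character vector of covariate (e.g. batch) levels;
#'   one all-ones covariate node is appended per level. `NULL` for none.
#' @param minGenes minimum surviving module size (default 5)
#' @return a list with elements `mask` (genes x latent binary matrix with
#'   dimnames), `layout` (a [LatentLayout-class]) and `collection` (the
#'   surviving, intersected modules)
#' @examples
#' gmc <- GeneModuleCollection(list(M1 = c("G1", "G2")))
#' m <- buildMask(gmc, c("G1", "G2", "G3"), minGenes = 1)
#' m$mask
#' @export
buildMask <- function(collection, genes, nFC = 0L, covariateLevels = NULL,
                      minGenes = 5L) {
    stopifnot(is(collection, "GeneModuleCollection"))
    genes <- as.character(genes)
    if (length(genes) == 0L) stop("gene universe must be non-empty")
    if (anyDuplicated(genes)) stop("gene universe contains duplicates")
    nFC <- as.integer(nFC)
    if (nFC < 0L) stop("nFC must be >= 0")
    covariateLevels <- as.character(covariateLevels %||% character(0))
    nCov <- length(covariateLevels)

    kept <- lapply(collection@modules, intersect, x = genes)
    # intersect(x=genes, y=module) keeps gene-universe order; we only need
    # membership so order is irrelevant, but determinism matters
    sizes <- vapply(kept, length, 1L)
    drop <- sizes < minGenes
    if (any(drop))
        warning(sum(drop), " module(s) dropped: fewer than ", minGenes,
                " member genes found in the dataset (",
                paste(head(names(kept)[drop], 5L), collapse = ", "),
                if (sum(drop) > 5L) ", ..." else "", ")")
    kept <- kept[!drop]
    if (length(kept) == 0L)
        stop("no gene module survives the intersection with the dataset; ",
             "lower minGenes or check gene identifier conventions ",
             "(e.g. symbol case; see readGMT(toupper=))")

    nGMV <- length(kept)
    total <- nGMV + nFC + nCov
    mask <- matrix(0, nrow = length(genes), ncol = total)
    for (j in seq_len(nGMV))
        mask[match(kept[[j]], genes), j] <- 1
    if (nFC + nCov > 0L)
        mask[, nGMV + seq_len(nFC + nCov)] <- 1

    fcNames <- if (nFC > 0L) paste0("FC_", seq_len(nFC)) else character(0)
    covNames <- if (nCov > 0L) paste0("COV_", covariateLevels)
                else character(0)
    latentNames <- c(names(kept), fcNames, covNames)
    dimnames(mask) <- list(genes, latentNames)

    layout <- new("LatentLayout",
        nGMV = nGMV, nFC = nFC, nCovariate = nCov,
        covariateLevels = covariateLevels,
        latentNames = latentNames,
        nodeKinds = c(rep("gmv", nGMV), rep("fc", nFC),
                      rep("covariate", nCov)))
    if (nFC > 16L)
        warning("nFC = ", nFC, " fully-connected nodes; more than 16 free ",
                "nodes can absorb biological signal that belongs to the ",
                "gene-module nodes")
    keptDesc <- collection@descriptions[!drop]
    list(mask = mask, layout = layout,
         collection = GeneModuleCollection(kept, keptDesc))
}

#' @rdname latentNames
#' @param x a LatentLayout or LatentPosterior
#' @export
setMethod("latentNames", "LatentLayout", function(x) x@latentNames)

#' @rdname nodeKinds
#' @param x a LatentLayout or LatentPosterior
#' @export
setMethod("nodeKinds", "LatentLayout", function(x) x@nodeKinds)

#' @rdname latentNames
#' @export
setMethod("latentNames", "LatentPosterior", function(x) x@latentNames)

#' @rdname nodeKinds
#' @export
setMethod("nodeKinds", "LatentPosterior", function(x) x@nodeKinds)

setMethod("show", "LatentLayout", function(object) {
    cat("LatentLayout:", object@nGMV, "GMV +", object@nFC, "FC +",
        object@nCovariate, "covariate nodes\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
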