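#' Save a model checkpoint
#'
#' Writes a directory holding the full parameter set (`weights.rds`) and a
#' library-agnostic JSON sidecar (`model.json`) recording gene order, latent
#' node names and kinds, covariate levels, architecture config and
#' parameter shapes, so a projection can be reproduced in a later session.
#'
#' @param model a [VegaModel-class]
#' @param dir checkpoint directory (created if missing)
#' @return `dir`, invisibly
#' @export
saveVegaModel <- function(model, dir) {
    stopifnot(is(model, "VegaModel"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(list(params = model@params, mask = model@mask),
            file.path(dir, "weights.rds"))
    lay <- model@layout
    shapes <- lapply(model@params, function(p) {
        if (is.list(p)) lapply(p, dim) else dim(p) %||% length(p)
    })
    meta <- list(
        format = "vegar-checkpoint-1",
        package_version = as.character(packageVersion("vegar")),
        genes = model@genes,
        latent_names = lay@latentNames,
        node_kinds = lay@nodeKinds,
        covariate_levels = lay@covariateLevels,
        config = model@config,
        trained = model@trained,
        shapes = shapes)
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [saveVegaModel()]
#' @return a [VegaModel-class]
#' @export
loadVegaModel <- function(dir) {
    wfile <- file.path(dir, "weights.rds")
    mfile <- file.path(dir, "model.json")
    if (!file.exists(wfile) || !file.exists(mfile))
        stop("not a model checkpoint directory: ", dir)
    w <- readRDS(wfile)
    meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    kinds <- meta$node_kinds
    layout <- new("LatentLayout",
        nGMV = sum(kinds == "gmv"),
        nFC = sum(kinds == "fc"),
        nCovariate = sum(kinds == "covariate"),
        covariateLevels = as.character(meta$covariate_levels %||%
                                       character(0)),
        latentNames = meta$latent_names,
        nodeKinds = kinds)
    cfg <- meta$config
    cfg$decoderBias <- isTRUE(cfg$decoderBias)
    new("VegaModel", params = w$params, mask = w$mask, layout = layout,
        genes = meta$genes, config = cfg, trained = isTRUE(meta$trained))
}
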