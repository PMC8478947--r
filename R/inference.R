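#' Gene-module activities for (possibly out-of-sample) data
#'
#' Projects a dataset through the trained encoder and returns the posterior
#' means of the gene-module nodes only — a cells x modules activity matrix.
#' Input genes are reconciled to the training gene order: genes missing from
#' the data are zero-filled with a warning, genes unseen at training are
#' dropped, and fewer than 50% surviving training genes is an error since
#' the projection would be meaningless. Deterministic (dropout disabled).
#'
#' @param model a trained [VegaModel-class]
#' @param data a `SummarizedExperiment` or cells x genes matrix with gene
#'   names
#' @param covariates optional integer covariate codes for matrix input
#' @param ... unused
#' @return cells x modules numeric matrix of activities
#' @rdname gmvActivities
#' @export
setMethod("gmvActivities", "VegaModel", function(model, data,
                                                 covariates = NULL, ...) {
    X <- .alignedCellMatrix(model, data, strict = FALSE)
    if (is(data, "SummarizedExperiment") && model@layout@nCovariate > 0L)
        covariates <- .covariateCodes(model, data)
    post <- encode(model, X, covariates = covariates)
    idx <- which(model@layout@nodeKinds == "gmv")
    post@mu[, idx, drop = FALSE]
})

#' Reconstruct expression through the masked decoder
#'
#' Decodes the posterior means (covariate coordinates set from each cell's
#' label), yielding the model's denoised view of the data. Gene
#' reconciliation follows [gmvActivities()].
#'
#' @param model a trained [VegaModel-class]
#' @param data a `SummarizedExperiment` or cells x genes matrix
#' @param covariates optional integer covariate codes for matrix input
#' @param ... unused
#' @return cells x genes numeric matrix in training gene order
#' @rdname reconstructExpression
#' @export
setMethod("reconstructExpression", "VegaModel",
          function(model, data, covariates = NULL, ...) {
    X <- .alignedCellMatrix(model, data, strict = FALSE)
    if (is(data, "SummarizedExperiment") && model@layout@nCovariate > 0L)
        covariates <- .covariateCodes(model, data)
    post <- encode(model, X, covariates = covariates)
    mu <- post@mu
    lay <- model@layout
    if (lay@nCovariate > 0L) {
        idx <- which(lay@nodeKinds == "covariate")
        mu[, idx] <- .oneHot(covariates, lay@nCovariate)
    }
    out <- decode(model, mu)
    rownames(out) <- rownames(X)
    out
})

#' Write an activity matrix as TSV
#'
#' @param activities cells x modules matrix from [gmvActivities()]
#' @param path output TSV path; cells in rows, module names in the header
#' @return `path`, invisibly
#' @export
writeActivities <- function(activities, path) {
    df <- data.frame(cell = rownames(activities) %||%
                         paste0("cell_", seq_len(nrow(activities))),
                     activities, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
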