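#' Assemble an expression dataset
#'
#' Wraps a log-normalized expression matrix and per-cell annotations into a
#' [SummarizedExperiment::SummarizedExperiment] with one assay named
#' `"logexpr"` (genes in rows, cells in columns) — the container every
#' model-facing function in this package consumes.
#'
#' @param X numeric matrix of log-normalized expression. Orientation is
#'   declared by `genesInRows`.
#' @param cellData a `data.frame`/`DataFrame` of per-cell categorical
#'   annotations (e.g. `condition`, `cell_type`, `batch`), or `NULL`
#' @param genesInRows `TRUE` (default) if `X` is genes x cells,
#'   `FALSE` if cells x genes
#' @return a `SummarizedExperiment`
#' @export
makeExpressionDataset <- function(X, cellData = NULL, genesInRows = TRUE) {
    X <- as.matrix(X)
    if (!genesInRows) X <- t(X)
    if (is.null(rownames(X)))
        rownames(X) <- paste0("gene_", seq_len(nrow(X)))
    if (is.null(colnames(X)))
        colnames(X) <- paste0("cell_", seq_len(ncol(X)))
    if (is.null(cellData))
        cellData <- S4Vectors::DataFrame(row.names = colnames(X))
    else {
        cellData <- S4Vectors::DataFrame(cellData)
        if (nrow(cellData) != ncol(X))
            stop("cellData must have one row per cell (", ncol(X),
                 " cells, ", nrow(cellData), " annotation rows)")
        rownames(cellData) <- colnames(X)
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(logexpr = X), colData = cellData)
}

#' Read a dense CSV expression matrix
#'
#' Expects cells in rows and genes in columns, with cell identifiers in the
#' first column and gene identifiers in the header — the layout written by
#' [writeExpressionCSV()] and by common exporters.
#'
#' @param path CSV file of expression values
#' @param cellDataPath optional TSV of per-cell annotations (header row;
#'   rows aligned with the expression rows)
#' @return a `SummarizedExperiment` (see [makeExpressionDataset()])
#' @export
readExpressionCSV <- function(path, cellDataPath = NULL) {
    if (!file.exists(path)) stop("expression CSV not found: ", path)
    tab <- read.csv(path, row.names = 1L, check.names = FALSE)
    X <- as.matrix(tab)
    storage.mode(X) <- "double"
    cd <- NULL
    if (!is.null(cellDataPath)) {
        if (!file.exists(cellDataPath))
            stop("cell annotation file not found: ", cellDataPath)
        cd <- read.table(cellDataPath, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    }
    makeExpressionDataset(X, cellData = cd, genesInRows = FALSE)
}

#' Write a dataset as dense CSV (+ cell annotations TSV)
#'
#' @param se a `SummarizedExperiment` with a `"logexpr"` assay
#' @param path output CSV path (cells x genes)
#' @param cellDataPath optional output TSV path for `colData`
#' @return `path`, invisibly
#' @export
writeExpressionCSV <- function(se, path, cellDataPath = NULL) {
    X <- t(exprMatrix(se))
    df <- data.frame(cell = rownames(X), X, check.names = FALSE)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    if (!is.null(cellDataPath)) {
        cd <- as.data.frame(SummarizedExperiment::colData(se))
        write.table(cd, cellDataPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Read an MTX-format expression directory
#'
#' Reads the MatrixMarket triplet convention (`matrix.mtx` with genes in
#' rows and cells in columns, `features.tsv` gene identifiers,
#' `barcodes.tsv` cell identifiers, optional `obs.tsv` per-cell
#' annotations with a header row).
#'
#' @param dir directory containing the files above
#' @return a `SummarizedExperiment`
#' @export
readExpressionMTX <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
    X <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(file.path(dir, "features.tsv"))
    genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    if (length(genes) != nrow(X) || length(cells) != ncol(X))
        stop("features/barcodes do not match matrix dimensions")
    dimnames(X) <- list(genes, cells)
    obs <- file.path(dir, "obs.tsv")
    cd <- if (file.exists(obs))
        read.table(obs, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    else NULL
    makeExpressionDataset(X, cellData = cd)
}

#' Write a dataset as an MTX directory
#'
#' @param se a `SummarizedExperiment` with a `"logexpr"` assay
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeExpressionMTX <- function(se, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    X <- exprMatrix(se)
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(X), file.path(dir, "features.tsv"))
    writeLines(colnames(X), file.path(dir, "barcodes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (ncol(cd) > 0L)
        write.table(cd, file.path(dir, "obs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Extract the log-expression assay (genes x cells)
#'
#' @param se a `SummarizedExperiment`
#' @return numeric matrix, genes in rows
#' @export
exprMatrix <- function(se) {
    stopifnot(is(se, "SummarizedExperiment"))
    nm <- SummarizedExperiment::assayNames(se)
    a <- if ("logexpr" %in% nm) "logexpr" else nm[1L]
    as.matrix(SummarizedExperiment::assay(se, a))
}

# cells x genes orientation used by the numerical core
.cellMatrix <- function(se) t(exprMatrix(se))

# per-cell covariate (batch) codes for a model; integer index into
# covariateLevels, or NULL when the model carries no covariate nodes
.covariateCodes <- function(model, se) {
    layout <- model@layout
    if (layout@nCovariate == 0L) return(NULL)
    cd <- SummarizedExperiment::colData(se)
    col <- model@config$covariateColumn %||% "batch"
    if (!col %in% colnames(cd))
        stop("dataset lacks the covariate column '", col,
             "' the model was conditioned on")
    lv <- as.character(cd[[col]])
    codes <- match(lv, layout@covariateLevels)
    if (anyNA(codes))
        stop("covariate level(s) unseen at training: ",
             paste(unique(lv[is.na(codes)]), collapse = ", "))
    codes
}
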