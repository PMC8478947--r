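#' Configuration for the synthetic module-structured generator
#'
#' Describes a synthetic single-cell dataset built from the same generative
#' picture the model assumes: per-cell module activities drawn from
#' condition-specific Gaussian priors, sparse nonnegative gene loadings
#' supported exactly on the emitted gene modules, optional hidden factors
#' driving the unannotated genes, additive per-gene batch offsets, and
#' Gaussian observation noise on a log-normalized-like scale (the matrix is
#' shifted to be nonnegative).
#'
#' Defaults describe a two-condition experiment of 2000 cells, 1000 genes
#' and 20 modules of 40 genes with 10% overlap between consecutive modules.
#'
#' @param nCellsPerGroup cells per (condition x batch) cell (default 1000)
#' @param conditions condition labels (default `c("ctrl", "stim")`)
#' @param nBatches number of batches (default 1; offsets only drawn when
#'   > 1)
#' @param nGenes total genes (default 1000)
#' @param nModules number of gene modules (default 20)
#' @param genesPerModule genes per module (default 40)
#' @param overlapFraction fraction of a module's genes shared with the
#'   previous module (default 0.1)
#' @param activityMean,activityStd Gaussian prior on module activities
#'   (defaults 0, 1)
#' @param loadingScale scale of the nonnegative loadings (default 1);
#'   loadings are Uniform(0.3, 1) x `loadingScale`
#' @param noiseStd observation noise standard deviation (default 0.5)
#' @param batchOffsetStd standard deviation of per-gene batch offsets
#'   (default 0.3; used only when `nBatches > 1`)
#' @param nHiddenFactors latent factors driving the unannotated genes
#'   (default 2); emulates biology the module annotation does not cover
#' @param baselineShape,baselineScale gamma parameters of the per-gene
#'   baseline expression level (defaults 1.5, 1), reproducing the
#'   right-skewed spread of mean log-normalized expression across genes;
#'   `baselineShape = 0` disables baselines
#' @param differential named numeric vector: activity-mean shift applied to
#'   the named modules in the second condition (see [plantDifferential()])
#' @param seed integer seed; the whole dataset is a pure function of the
#'   config
#' @return a list of class `vegaSimConfig`
#' @export
vegaSimConfig <- function(nCellsPerGroup = 1000L,
                          conditions = c("ctrl", "stim"),
                          nBatches = 1L, nGenes = 1000L, nModules = 20L,
                          genesPerModule = 40L, overlapFraction = 0.1,
                          activityMean = 0, activityStd = 1,
                          loadingScale = 1, noiseStd = 0.5,
                          batchOffsetStd = 0.3, nHiddenFactors = 2L,
                          baselineShape = 1.5, baselineScale = 1,
                          differential = numeric(0), seed = 0L) {
    stopifnot(nCellsPerGroup >= 1, length(conditions) >= 1, nBatches >= 1,
              nGenes >= 1, nModules >= 1, genesPerModule >= 1,
              overlapFraction >= 0, overlapFraction < 1,
              activityStd > 0, loadingScale > 0, noiseStd >= 0,
              batchOffsetStd >= 0, nHiddenFactors >= 0,
              baselineShape >= 0, baselineScale > 0)
    ov <- floor(overlapFraction * genesPerModule)
    needed <- genesPerModule + (nModules - 1L) * (genesPerModule - ov)
    if (needed > nGenes)
        stop("module construction impossible: ", nModules, " modules of ",
             genesPerModule, " genes at overlap ", overlapFraction,
             " need ", needed, " genes but nGenes = ", nGenes)
    if (length(differential) > 0L) {
        if (is.null(names(differential)) || any(names(differential) == ""))
            stop("differential must be a named numeric vector")
        if (length(conditions) < 2L)
            stop("differential effects need at least 2 conditions")
    }
    structure(list(nCellsPerGroup = as.integer(nCellsPerGroup),
                   conditions = as.character(conditions),
                   nBatches = as.integer(nBatches),
                   nGenes = as.integer(nGenes),
                   nModules = as.integer(nModules),
                   genesPerModule = as.integer(genesPerModule),
                   overlapFraction = overlapFraction,
                   activityMean = activityMean, activityStd = activityStd,
                   loadingScale = loadingScale, noiseStd = noiseStd,
                   batchOffsetStd = batchOffsetStd,
                   nHiddenFactors = as.integer(nHiddenFactors),
                   baselineShape = baselineShape,
                   baselineScale = baselineScale,
                   differential = differential, seed = as.integer(seed)),
              class = "vegaSimConfig")
}

.simModuleNames <- function(n) sprintf("module_%02d", seq_len(n))

#' Plant differential module activity into a config
#'
#' Returns a config whose named modules differ in mean activity between the
#' first and second condition by `effectSize` (added to the second
#' condition). An effect of zero leaves the generative distribution
#' unchanged.
#'
#' @param config a [vegaSimConfig()]
#' @param moduleIds module names (e.g. `"module_03"`) to perturb
#' @param effectSize scalar or per-module vector of activity-mean shifts
#' @return the modified config
#' @export
plantDifferential <- function(config, moduleIds, effectSize) {
    stopifnot(inherits(config, "vegaSimConfig"))
    valid <- .simModuleNames(config$nModules)
    bad <- setdiff(moduleIds, valid)
    if (length(bad) > 0L)
        stop("unknown module id(s): ", paste(bad, collapse = ", "))
    if (length(config$conditions) < 2L)
        stop("differential effects need at least 2 conditions")
    eff <- rep_len(effectSize, length(moduleIds))
    names(eff) <- moduleIds
    config$differential <- eff
    config
}

#' Simulate a module-structured single-cell dataset
#'
#' Draws per-cell module activities Z from condition-specific normal priors,
#' builds sparse nonnegative loadings W supported on the emitted modules,
#' and emits `X = Z W' + hidden-factor signal + batch offset + noise`,
#' shifted so the minimum is zero (log-normalized-like scale). Genes beyond
#' the modules' span are unannotated: they carry only noise and, if
#' configured, hidden-factor signal — the raison d'etre of the extra
#' fully-connected latent nodes.
#'
#' @param config a [vegaSimConfig()]
#' @return list with elements `data` (a `SummarizedExperiment` with
#'   `condition` and `batch` in `colData`), `modules` (a
#'   [GeneModuleCollection-class]), and `truth` (list: `Z` true activities,
#'   `W` true loadings, `baseline` per-gene offsets, `condition`, `batch`,
#'   `differential`)
#' @examples
#' sim <- simulateModuleData(vegaSimConfig(nCellsPerGroup = 50,
#'     nGenes = 120, nModules = 3, genesPerModule = 30, seed = 1))
#' sim$data
#' @export
simulateModuleData <- function(config) {
    stopifnot(inherits(config, "vegaSimConfig"))
    withr::with_seed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
    gpm <- cfg$genesPerModule
    ov <- floor(cfg$overlapFraction * gpm)
    geneNames <- sprintf("gene_%04d", seq_len(cfg$nGenes))
    modNames <- .simModuleNames(cfg$nModules)
    members <- lapply(seq_len(cfg$nModules), function(m) {
        start <- 1L + (m - 1L) * (gpm - ov)
        start:(start + gpm - 1L)
    })
    modules <- GeneModuleCollection(
        setNames(lapply(members, function(i) geneNames[i]), modNames),
        rep("synthetic module", cfg$nModules))

    W <- matrix(0, cfg$nGenes, cfg$nModules,
                dimnames = list(geneNames, modNames))
    for (m in seq_len(cfg$nModules))
        W[members[[m]], m] <- runif(gpm, 0.3, 1) * cfg$loadingScale

    baseline <- if (cfg$baselineShape > 0)
        stats::rgamma(cfg$nGenes, shape = cfg$baselineShape,
                      scale = cfg$baselineScale)
    else numeric(cfg$nGenes)
    names(baseline) <- geneNames

    groups <- expand.grid(condition = cfg$conditions,
                          batch = paste0("batch_", seq_len(cfg$nBatches)),
                          stringsAsFactors = FALSE)
    n <- cfg$nCellsPerGroup * nrow(groups)
    condition <- rep(groups$condition, each = cfg$nCellsPerGroup)
    batch <- rep(groups$batch, each = cfg$nCellsPerGroup)
    cellNames <- sprintf("cell_%05d", seq_len(n))

    actMean <- matrix(cfg$activityMean, length(cfg$conditions),
                      cfg$nModules,
                      dimnames = list(cfg$conditions, modNames))
    if (length(cfg$differential) > 0L)
        actMean[2L, names(cfg$differential)] <-
            actMean[2L, names(cfg$differential)] + cfg$differential

    condIdx <- match(condition, cfg$conditions)
    Z <- matrix(rnorm(n * cfg$nModules, sd = cfg$activityStd),
                n, cfg$nModules, dimnames = list(cellNames, modNames))
    Z <- Z + actMean[condIdx, , drop = FALSE]

    X <- Z %*% t(W)
    X <- sweep(X, 2L, baseline, "+")
    used <- max(members[[cfg$nModules]])
    if (cfg$nHiddenFactors > 0L && used < cfg$nGenes) {
        unannot <- (used + 1L):cfg$nGenes
        H <- matrix(rnorm(n * cfg$nHiddenFactors), n, cfg$nHiddenFactors)
        V <- matrix(0, cfg$nGenes, cfg$nHiddenFactors)
        V[unannot, ] <- runif(length(unannot) * cfg$nHiddenFactors,
                              0.3, 1) * cfg$loadingScale
        X <- X + H %*% t(V)
    }
    if (cfg$nBatches > 1L && cfg$batchOffsetStd > 0) {
        offsets <- matrix(rnorm(cfg$nGenes * cfg$nBatches,
                                sd = cfg$batchOffsetStd),
                          cfg$nGenes, cfg$nBatches,
                          dimnames = list(geneNames,
                                          unique(groups$batch)))
        X <- X + t(offsets[, match(batch, colnames(offsets)),
                           drop = FALSE])
    }
    if (cfg$noiseStd > 0)
        X <- X + matrix(rnorm(n * cfg$nGenes, sd = cfg$noiseStd),
                        n, cfg$nGenes)
    X <- X - min(X)
    dimnames(X) <- list(cellNames, geneNames)

    se <- makeExpressionDataset(X, genesInRows = FALSE,
        cellData = data.frame(condition = condition, batch = batch,
                              stringsAsFactors = FALSE))
    list(data = se, modules = modules,
         truth = list(Z = Z, W = W, baseline = baseline,
                      condition = condition, batch = batch,
                      differential = cfg$differential))
}
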