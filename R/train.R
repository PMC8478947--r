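#' Training configuration
#'
#' Defaults follow the published training protocol for this architecture:
#' learning rate 5e-4, at most 300 epochs, early stopping on validation
#' objective with patience 20, and an 80% train split. Batch size and KL
#' weight are implementation defaults.
#'
#' @param learningRate Adam learning rate (default 5e-4)
#' @param maxEpochs maximum number of epochs (default 300); 0 returns the
#'   initialized model untouched
#' @param batchSize minibatch size (default 128)
#' @param trainFraction fraction of cells used for training, the rest for
#'   validation (default 0.8)
#' @param patience early-stopping patience in epochs on the validation
#'   objective (default 20); `Inf` disables early stopping
#' @param klWeight multiplier on the KL term (default 1)
#' @param klWarmup epochs over which the KL weight ramps linearly from 0 to
#'   `klWeight` (default 0 = off)
#' @param reconReduction `"sum"` (default): reconstruction error summed over
#'   genes, averaged over cells, commensurate with the KL summed over latent
#'   dimensions; `"mean"` additionally divides by the gene count (then
#'   `klWeight` should be scaled down accordingly)
#' @param seed integer seed governing the split, shuffling, dropout and
#'   latent sampling
#' @return a list of class `vegaTrainConfig`
#' @export
vegaTrainConfig <- function(learningRate = 5e-4, maxEpochs = 300L,
                            batchSize = 128L, trainFraction = 0.8,
                            patience = 20L, klWeight = 1.0, klWarmup = 0L,
                            reconReduction = c("sum", "mean"), seed = 0L) {
    reconReduction <- match.arg(reconReduction)
    stopifnot(learningRate > 0, maxEpochs >= 0, batchSize >= 1,
              trainFraction > 0, trainFraction <= 1,
              patience >= 1, klWeight >= 0, klWarmup >= 0)
    structure(list(learningRate = learningRate,
                   maxEpochs = as.integer(maxEpochs),
                   batchSize = as.integer(batchSize),
                   trainFraction = trainFraction, patience = patience,
                   klWeight = klWeight, klWarmup = as.integer(klWarmup),
                   reconReduction = reconReduction,
                   seed = as.integer(seed)),
              class = "vegaTrainConfig")
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian q = N(mu, diag(sigma^2)) and prior p = N(0, I),
#' KL(q || p) = sum_j (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2) / 2.
#' Nonnegative; zero exactly when mu = 0 and sigma = 1.
#'
#' @param mu numeric vector (or cells x latent matrix) of means
#' @param sigma matching vector/matrix of standard deviations, > 0
#' @return scalar KL for vector input; per-cell vector for matrix input
#' @examples
#' klStandardNormal(0, 1)   # 0
#' klStandardNormal(1, 1)   # 0.5
#' @export
klStandardNormal <- function(mu, sigma) {
    if (any(sigma <= 0)) stop("sigma must be strictly positive")
    term <- 0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))
    if (is.matrix(mu)) rowSums(term) else sum(term)
}

# Forward + backward pass for one minibatch.
# X: cells x genes; covOnehot: n x nCov one-hot (or NULL); training mode
# draws dropout masks and eps from the current RNG stream. Returns loss
# terms and, if grad=TRUE, gradients shaped like the params.
.lossGrads <- function(params, X, covOnehot, mask, layout, config, cfgTrain,
                       klWeight, training = TRUE, grad = TRUE) {
    n <- nrow(X); g <- ncol(X)
    nL <- length(params$encW)
    idxCov <- which(layout@nodeKinds == "covariate")
    idxNC <- which(layout@nodeKinds != "covariate")
    L <- length(layout@nodeKinds)

    dropMasks <- NULL
    pDrop <- config$dropoutRate
    if (training && pDrop > 0) {
        dropMasks <- lapply(seq_len(nL), function(l) {
            nh <- ncol(params$encW[[l]])
            matrix((runif(n * nh) >= pDrop) / (1 - pDrop), n, nh)
        })
    } else if (training) {
        dropMasks <- lapply(seq_len(nL), function(l)
            matrix(1, n, ncol(params$encW[[l]])))
    }

    fw <- .encForward(params, X, dropMasks)
    mu <- fw$mu; lv <- fw$logvar
    sigma <- exp(0.5 * lv)
    eps <- matrix(rnorm(n * L), n, L)
    z <- mu + sigma * eps

    latMask <- NULL
    pLat <- config$latentDropout
    if (training && pLat > 0 && length(idxNC) > 0L) {
        latMask <- matrix((runif(n * length(idxNC)) >= pLat) / (1 - pLat),
                          n, length(idxNC))
        z[, idxNC] <- z[, idxNC] * latMask
    }
    if (length(idxCov) > 0L) z[, idxCov] <- covOnehot

    D <- params$decoderW
    xhat <- z %*% t(D)
    if (isTRUE(config$decoderBias))
        xhat <- sweep(xhat, 2L, params$decoderB, "+")

    scale <- if (cfgTrain$reconReduction == "mean") 1 / (n * g) else 1 / n
    resid <- xhat - X
    recon <- 0.5 * sum(resid^2) * scale
    klPer <- 0.5 * (mu[, idxNC, drop = FALSE]^2 +
                    sigma[, idxNC, drop = FALSE]^2 - 1 -
                    lv[, idxNC, drop = FALSE])
    kl <- sum(klPer) / n
    loss <- recon + klWeight * kl
    if (!is.finite(loss)) {
        bad <- if (!is.finite(recon)) "reconstruction" else "KL"
        stop("non-finite ", bad, " term in the objective")
    }
    out <- list(loss = loss, recon = recon, kl = kl)
    if (!grad) return(out)

    gr <- list(encW = vector("list", nL), encB = vector("list", nL))
    dxhat <- resid * scale
    gr$decoderW <- crossprod(dxhat, z) * mask  # zero gradient off-mask
    gr$decoderB <- if (isTRUE(config$decoderBias)) colSums(dxhat)
                   else numeric(g)
    dz <- dxhat %*% D
    if (length(idxCov) > 0L) dz[, idxCov] <- 0
    if (!is.null(latMask)) dz[, idxNC] <- dz[, idxNC] * latMask

    dmu <- dz
    dlv <- dz * eps * sigma * 0.5
    if (length(idxNC) > 0L) {
        w <- klWeight / n
        dmu[, idxNC] <- dmu[, idxNC] + w * mu[, idxNC]
        dlv[, idxNC] <- dlv[, idxNC] + w * 0.5 * (sigma[, idxNC]^2 - 1)
    }
    if (length(idxCov) > 0L) {  # covariate heads receive no learning signal
        dmu[, idxCov] <- 0
        dlv[, idxCov] <- 0
    }
    dlv <- dlv * fw$lvMask

    H <- fw$A[[nL + 1L]]
    gr$muW <- crossprod(H, dmu); gr$muB <- colSums(dmu)
    gr$lvW <- crossprod(H, dlv); gr$lvB <- colSums(dlv)
    dH <- dmu %*% t(params$muW) + dlv %*% t(params$lvW)
    for (l in rev(seq_len(nL))) {
        if (!is.null(dropMasks)) dH <- dH * dropMasks[[l]]
        dZ <- dH * (fw$Zpre[[l]] > 0)
        gr$encW[[l]] <- crossprod(fw$A[[l]], dZ)
        gr$encB[[l]] <- colSums(dZ)
        if (l > 1L) dH <- dZ %*% t(params$encW[[l]])
    }
    out$grads <- gr
    out
}

#' Evaluate the training objective on a batch
#'
#' Returns the evidence lower bound and its two components for one batch,
#' using a single reparametrized Monte-Carlo draw per cell. The ELBO is
#' reported as `reconstruction - klWeight * kl`, where `reconstruction` is
#' the Gaussian log-likelihood term up to an additive constant (i.e. minus
#' the squared-error term). Deterministic for a fixed seed.
#'
#' @param model a [VegaModel-class]
#' @param batch cells x genes matrix in training gene order, or a
#'   `SummarizedExperiment`
#' @param covariates integer covariate codes (when needed and `batch` is a
#'   matrix)
#' @param klWeight KL multiplier (default 1)
#' @param seed integer seed for the Monte-Carlo draw
#' @return named numeric vector `c(elbo=, reconstruction=, kl=)`
#' @export
elboTerms <- function(model, batch, covariates = NULL, klWeight = 1.0,
                      seed = 0L) {
    X <- .alignedCellMatrix(model, batch, strict = TRUE)
    if (nrow(X) == 0L) stop("batch must be non-empty")
    if (is(batch, "SummarizedExperiment") && model@layout@nCovariate > 0L)
        covariates <- .covariateCodes(model, batch)
    covOnehot <- if (model@layout@nCovariate > 0L) {
        if (is.null(covariates)) stop("covariate codes required")
        .oneHot(covariates, model@layout@nCovariate)
    } else NULL
    res <- withr::with_seed(as.integer(seed),
        .lossGrads(model@params, X, covOnehot, model@mask, model@layout,
                   model@config, list(reconReduction = "sum"),
                   klWeight = klWeight, training = FALSE, grad = FALSE))
    c(elbo = -(res$recon + klWeight * res$kl),
      reconstruction = -res$recon, kl = res$kl)
}

.adamInit <- function(params) {
    zero <- function(x) {
        if (is.list(x)) lapply(x, zero) else x * 0
    }
    list(m = zero(params), v = zero(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8) {
    state$t <- state$t + 1L
    corr1 <- 1 - beta1^state$t
    corr2 <- 1 - beta2^state$t
    upd <- function(p, g, m, v) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        p <- p - lr * (m / corr1) / (sqrt(v / corr2) + epsilon)
        list(p = p, m = m, v = v)
    }
    for (nm in names(params)) {
        if (is.list(params[[nm]])) {
            for (l in seq_along(params[[nm]])) {
                r <- upd(params[[nm]][[l]], grads[[nm]][[l]],
                         state$m[[nm]][[l]], state$v[[nm]][[l]])
                params[[nm]][[l]] <- r$p
                state$m[[nm]][[l]] <- r$m
                state$v[[nm]][[l]] <- r$v
            }
        } else {
            r <- upd(params[[nm]], grads[[nm]], state$m[[nm]],
                     state$v[[nm]])
            params[[nm]] <- r$p
            state$m[[nm]] <- r$m
            state$v[[nm]] <- r$v
        }
    }
    list(params = params, state = state)
}

#' Train a gene-module VAE
#'
#' Minibatch Adam optimization of the negative ELBO with a random
#' train/validation split, early stopping on the validation ELBO, and the
#' decoder constraints (mask, nonnegativity) re-imposed after every step.
#' The returned model carries the parameters of the best validation epoch.
#'
#' @param model an initialized [VegaModel-class]
#' @param data a `SummarizedExperiment` whose genes match the model
#' @param config a [vegaTrainConfig()]
#' @param verbose print per-epoch progress every 25 epochs?
#' @return a list with elements `model` (trained [VegaModel-class]) and
#'   `history` (data.frame of per-epoch train/validation ELBO,
#'   reconstruction and KL terms, with the best epoch in
#'   `attr(history, "bestEpoch")`)
#' @export
trainVega <- function(model, data, config = vegaTrainConfig(),
                      verbose = FALSE) {
    stopifnot(is(model, "VegaModel"), inherits(config, "vegaTrainConfig"))
    X <- .alignedCellMatrix(model, data, strict = TRUE)
    lay <- model@layout
    codes <- if (lay@nCovariate > 0L) .covariateCodes(model, data) else NULL
    n <- nrow(X)
    emptyHist <- data.frame(epoch = integer(0), trainElbo = numeric(0),
                            trainRecon = numeric(0), trainKl = numeric(0),
                            valElbo = numeric(0), valRecon = numeric(0),
                            valKl = numeric(0))
    if (config$maxEpochs == 0L)
        return(list(model = model, history = emptyHist))
    # start the per-gene offset at the gene means so the optimizer spends
    # its budget on module structure, not on the global expression level
    if (isTRUE(model@config$decoderBias) && !model@trained)
        model@params$decoderB <- colMeans(X)

    runner <- function() {
        nVal <- if (config$trainFraction < 1) {
            v <- round((1 - config$trainFraction) * n)
            if (v < 1L)
                stop("validation split is empty; lower trainFraction")
            v
        } else 0L
        idx <- sample.int(n)
        valIdx <- if (nVal > 0L) idx[seq_len(nVal)] else integer(0)
        trIdx <- setdiff(idx, valIdx)
        if (length(trIdx) == 0L) stop("training split is empty")

        params <- model@params
        state <- .adamInit(params)
        hist <- vector("list", config$maxEpochs)
        best <- list(elbo = -Inf, params = params, epoch = 0L)
        wait <- 0L

        evalSplit <- function(params, rows) {
            if (length(rows) == 0L) return(c(NA_real_, NA_real_, NA_real_))
            cov <- if (!is.null(codes))
                .oneHot(codes[rows], lay@nCovariate) else NULL
            r <- .lossGrads(params, X[rows, , drop = FALSE], cov,
                            model@mask, lay, model@config, config,
                            klWeight = config$klWeight, training = FALSE,
                            grad = FALSE)
            c(-(r$recon + config$klWeight * r$kl), -r$recon, r$kl)
        }

        lastEpoch <- 0L
        for (epoch in seq_len(config$maxEpochs)) {
            klW <- if (config$klWarmup > 0L)
                config$klWeight * min(1, epoch / config$klWarmup)
            else config$klWeight
            ord <- trIdx[sample.int(length(trIdx))]
            starts <- seq(1L, length(ord), by = config$batchSize)
            epochLoss <- 0; epochRecon <- 0; epochKl <- 0
            for (s in starts) {
                rows <- ord[s:min(s + config$batchSize - 1L, length(ord))]
                cov <- if (!is.null(codes))
                    .oneHot(codes[rows], lay@nCovariate) else NULL
                r <- .lossGrads(params, X[rows, , drop = FALSE], cov,
                                model@mask, lay, model@config, config,
                                klWeight = klW, training = TRUE, grad = TRUE)
                if (!is.finite(r$loss))
                    stop("training diverged at epoch ", epoch)
                st <- .adamStep(params, r$grads, state, config$learningRate)
                params <- st$params; state <- st$state
                params$decoderW <- pmax(params$decoderW, 0) * model@mask
                wRows <- length(rows) / length(trIdx)
                epochLoss <- epochLoss + r$loss * wRows
                epochRecon <- epochRecon + r$recon * wRows
                epochKl <- epochKl + r$kl * wRows
            }
            val <- evalSplit(params, valIdx)
            hist[[epoch]] <- data.frame(
                epoch = epoch, trainElbo = -epochLoss,
                trainRecon = -epochRecon, trainKl = epochKl,
                valElbo = val[1L], valRecon = val[2L], valKl = val[3L])
            lastEpoch <- epoch
            if (verbose && epoch %% 25L == 0L)
                message(sprintf("epoch %d: train ELBO %.3f, val ELBO %.3f",
                                epoch, -epochLoss, val[1L]))
            monitor <- if (nVal > 0L) val[1L] else -epochLoss
            if (monitor > best$elbo + 1e-10) {
                best <- list(elbo = monitor, params = params, epoch = epoch)
                wait <- 0L
            } else {
                wait <- wait + 1L
                if (is.finite(config$patience) && wait >= config$patience)
                    break
            }
        }
        history <- do.call(rbind, hist[seq_len(lastEpoch)])
        attr(history, "bestEpoch") <- best$epoch
        list(params = best$params, history = history)
    }
    res <- withr::with_seed(config$seed, runner())

    model@params <- res$params
    model@params$decoderW <- pmax(model@params$decoderW, 0) * model@mask
    dimnames(model@params$decoderW) <- dimnames(model@mask)
    model@trained <- TRUE
    model@config$trainConfig <- unclass(config)
    list(model = model, history = res$history)
}
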