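test_that("model construction honors mask shape and seeding contract", {
    gmc <- GeneModuleCollection(list(
        M1 = c("G1", "G2", "G3"), M2 = c("G3", "G4", "G5"),
        M3 = c("G1", "G5", "G6")))
    bm <- buildMask(gmc, paste0("G", 1:8), nFC = 1L, minGenes = 3L)
    m <- vegaModel(bm, nHidden = 16L, seed = 42L)
    expect_identical(dim(m@params$decoderW), c(8L, 4L))
    expect_identical(latentNames(m), c("M1", "M2", "M3", "FC_1"))

    # bitwise-identical re-initialization with the same seed
    m2 <- vegaModel(bm, nHidden = 16L, seed = 42L)
    expect_identical(m@params, m2@params)
    m3 <- vegaModel(bm, nHidden = 16L, seed = 43L)
    expect_false(identical(m@params, m3@params))

    # layout inconsistent with the mask columns is rejected
    expect_error(vegaModel(bm$mask[, 1:3], bm$layout, nHidden = 8L),
                 "latent nodes")
})

test_that("masked decoder entries are zero from initialization", {
    set.seed(77)
    genes <- sprintf("g%03d", 1:100)
    mods <- setNames(lapply(1:10, function(i) sample(genes, 15L)),
                     paste0("m", 1:10))
    bm <- buildMask(GeneModuleCollection(mods), genes, minGenes = 5L)
    m <- vegaModel(bm, nHidden = 8L, seed = 1L)
    D <- m@params$decoderW
    expect_true(all(D[bm$mask == 0] == 0))
    expect_gte(min(D), 0)
    # uniform init then nonnegativity clamp: at least the masked fraction
    # of entries is exactly zero
    expect_gte(mean(D == 0), mean(bm$mask == 0))
})

test_that("encode is deterministic, finite, and checks gene counts", {
    sim <- smallSim()
    m <- smallModel(sim)
    p1 <- encode(m, sim$data)
    p2 <- encode(m, sim$data)
    expect_identical(p1@mu, p2@mu)
    expect_identical(p1@sigma, p2@sigma)
    expect_true(all(is.finite(p1@mu)) && all(p1@sigma > 0))

    # constant input on an untrained model stays finite
    X0 <- matrix(1, 4, length(m@genes),
                 dimnames = list(NULL, m@genes))
    p0 <- encode(m, X0)
    expect_true(all(is.finite(p0@mu)) && all(is.finite(p0@sigma)))

    expect_error(encode(m, matrix(0, 3, 10)), "10 genes")
})

test_that("sampleLatent implements the reparametrization trick", {
    mu <- matrix(c(0, 1, -2, 0.5), 2, 2)
    sig <- matrix(c(1e-12, 1e-12, 1e-12, 1e-12), 2, 2)
    post <- new("LatentPosterior", mu = mu, sigma = sig,
                latentNames = c("a", "b"), nodeKinds = c("gmv", "gmv"))
    # vanishing sigma: z = mu exactly (to float precision)
    expect_equal(sampleLatent(post, 1), mu, tolerance = 1e-9)

    # moments over many draws
    post2 <- new("LatentPosterior",
                 mu = matrix(c(1, -1), 1, 2),
                 sigma = matrix(c(0.5, 2), 1, 2),
                 latentNames = c("a", "b"), nodeKinds = c("gmv", "gmv"))
    draws <- vapply(1:10000, function(s)
        sampleLatent(post2, s)[1, ], numeric(2))
    expect_lt(max(abs(rowMeans(draws) - c(1, -1)) / (c(0.5, 2) / 100)), 4)
    # chi-squared-style bound on the variance ratio at n = 1e4
    vr <- apply(draws, 1, var) / c(0.25, 4)
    expect_true(all(abs(vr - 1) < 0.06))
    # reproducible given seed
    expect_identical(sampleLatent(post2, 7), sampleLatent(post2, 7))
})

test_that("decode respects mask semantics and nonnegative monotonicity", {
    sim <- smallSim()
    m <- smallModel(sim)
    L <- ncol(m@mask)
    # zero latent input, bias disabled -> exactly zero output
    mNoBias <- smallModel(sim, nFC = 1L)
    mNoBias@config$decoderBias <- FALSE
    expect_true(all(decode(mNoBias, matrix(0, 3, L)) == 0))

    # perturbing one module's node only moves that module's genes
    z0 <- matrix(0, 1, L)
    z1 <- z0; z1[1, 2] <- 1.5
    delta <- decode(m, z1) - decode(m, z0)
    touched <- m@genes[m@mask[, 2] == 1]
    expect_true(all(abs(delta[1, setdiff(m@genes, touched)]) == 0))

    # nonnegative weights: raising z_j never lowers any reconstruction
    for (zv in seq(-2, 2, by = 0.5)) {
        za <- z0; za[1, 2] <- zv
        zb <- z0; zb[1, 2] <- zv + 0.5
        expect_true(all(decode(m, zb) - decode(m, za) >= 0))
    }
    expect_error(decode(m, matrix(0, 2, L + 1)), "latent dimension")
})

test_that("constrainDecoder clamps and is idempotent", {
    sim <- smallSim()
    m <- smallModel(sim)
    unmasked <- which(m@mask == 1)[1]
    masked <- which(m@mask == 0)[1]
    m@params$decoderW[unmasked] <- -0.3
    m@params$decoderW[masked] <- 0.8
    c1 <- constrainDecoder(m)
    expect_identical(c1@params$decoderW[unmasked], 0)
    expect_identical(c1@params$decoderW[masked], 0)
    c2 <- constrainDecoder(c1)
    expect_identical(c1@params$decoderW, c2@params$decoderW)
})

test_that("covariate posterior coordinates mirror the batch one-hot code", {
    sim <- smallSim(nBatches = 2L, batchOffsetStd = 0.5)
    bm <- buildMask(sim$modules, rownames(sim$data), nFC = 1L,
                    covariateLevels = c("batch_1", "batch_2"),
                    minGenes = 5L)
    m <- vegaModel(bm, nHidden = 16L, seed = 2L)
    post <- encode(m, sim$data)
    covIdx <- which(nodeKinds(post) == "covariate")
    b <- SummarizedExperiment::colData(sim$data)$batch
    onehot <- cbind(as.numeric(b == "batch_1"),
                    as.numeric(b == "batch_2"))
    expect_equal(unname(post@mu[, covIdx]), onehot)
})
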