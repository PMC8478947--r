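test_that("log-Bayes factor is the natural-log posterior odds", {
    # |K| = 3 corresponds to posterior odds exp(3), about 20:1
    p <- exp(3) / (1 + exp(3))
    mu <- matrix(c(rep(1, 50), rep(0, 50)), ncol = 1)
    expect_equal(exp(3), 20.0855, tolerance = 1e-4)
    # K = ln(p/(1-p)) recovered from a constructed probability
    expect_equal(log(p / (1 - p)), 3)
})

test_that("self-comparison gives p(H0) near 1/2 and K near 0", {
    set.seed(3)
    mu <- matrix(rnorm(40 * 3), 40, 3)
    sd_ <- matrix(runif(40 * 3, 0.5, 1), 40, 3)
    bf <- bayesFactorLatent(mu, sd_, mu, sd_, nPairs = 4000, nMc = 10,
                            seed = 1)
    expect_true(all(abs(bf$p_h0 - 0.5) < 0.03))
    expect_true(all(abs(bf$K) < 0.15))
    expect_true(all(bf$MD == 0))
})

test_that("well-separated posteriors drive K to large finite values", {
    muA <- matrix(10, 20, 2); muB <- matrix(0, 20, 2)
    sd_ <- matrix(0.1, 20, 2)
    bf <- bayesFactorLatent(muA, sd_, muB, sd_, nPairs = 1000, nMc = 5,
                            seed = 2)
    # p clamps at 1 - 1/(nPairs*nMc); K = ln((1-eps)/eps)
    expect_equal(bf$K, rep(log(4999), 2), tolerance = 1e-9)
    expect_true(all(is.finite(bf$K)))
    expect_equal(bf$MD, c(10, 10))
})

test_that("estimated p(H0) matches the normal-exceedance closed form", {
    # two Gaussian groups with fixed posteriors: P(z_a > z_b) =
    # Phi((mu_a - mu_b) / sqrt(s_a^2 + s_b^2))
    grid <- expand.grid(dmu = c(-2, -0.5, 0, 0.5, 2),
                        s = c(0.2, 0.5, 1, 2, 4))
    nPairs <- 4000; nMc <- 10
    for (i in seq_len(nrow(grid))) {
        dmu <- grid$dmu[i]; s <- grid$s[i]
        muA <- matrix(dmu, 30, 1); muB <- matrix(0, 30, 1)
        sdA <- matrix(s, 30, 1); sdB <- matrix(s, 30, 1)
        bf <- bayesFactorLatent(muA, sdA, muB, sdB, nPairs = nPairs,
                                nMc = nMc, seed = 100 + i)
        pTrue <- pnorm(dmu / sqrt(2 * s^2))
        mcse <- sqrt(max(pTrue * (1 - pTrue), 1e-6) / (nPairs * nMc))
        expect_lt(abs(bf$p_h0 - pTrue),
                  max(3 * mcse, 2 / (nPairs * nMc)))
    }
})

test_that("swapping the groups negates K and preserves MD", {
    set.seed(8)
    muA <- matrix(rnorm(30 * 4, 0.4), 30, 4)
    muB <- matrix(rnorm(25 * 4), 25, 4)
    sdA <- matrix(runif(30 * 4, 0.3, 1), 30, 4)
    sdB <- matrix(runif(25 * 4, 0.3, 1), 25, 4)
    f <- bayesFactorLatent(muA, sdA, muB, sdB, nPairs = 5000, seed = 4)
    r <- bayesFactorLatent(muB, sdB, muA, sdA, nPairs = 5000, seed = 5)
    se <- sqrt(f$p_h0 * (1 - f$p_h0) / 50000)
    seK <- se / pmax(f$p_h0 * (1 - f$p_h0), 1e-6)  # delta method on logit
    expect_true(all(abs(f$K + r$K) < 6 * seK + 0.05))
    expect_equal(f$MD, r$MD)
})

test_that("differentialActivity validates groups and returns metadata", {
    sim <- smallSim()
    model <- smallModel(sim)
    cond <- SummarizedExperiment::colData(sim$data)$condition
    res <- differentialActivity(model, sim$data,
                                groupA = cond == "ctrl",
                                groupB = cond == "stim",
                                nPairs = 200, nMc = 4, seed = 1)
    expect_s4_class(res, "DFrame")
    expect_identical(nrow(res), 5L)
    expect_true(all(c("gmv", "p_h0", "K", "MD", "significant") %in%
                    colnames(res)))
    md <- S4Vectors::metadata(res)
    expect_identical(md$nA, sum(cond == "ctrl"))
    expect_identical(md$nPairs, 200L)

    expect_error(differentialActivity(model, sim$data,
                                      groupA = rep(FALSE, 300),
                                      groupB = cond == "stim"),
                 "empty")
    expect_error(differentialActivity(model, sim$data,
                                      groupA = cond == "ctrl",
                                      groupB = rep(TRUE, 300)),
                 "overlap")
})

test_that("one-vs-rest flips the sign of K for two categories", {
    sim <- smallSim()
    model <- smallModel(sim)
    res <- oneVsRest(model, sim$data, "condition", nPairs = 1500,
                     nMc = 5, seed = 2)
    expect_named(res, c("ctrl", "stim"))
    # antisymmetry within Monte-Carlo tolerance
    expect_true(all(abs(res$ctrl$K + res$stim$K) < 0.6))
    expect_equal(res$ctrl$MD, res$stim$MD)
    expect_error(oneVsRest(model, sim$data, rep("one", 300)),
                 "2 categories")
})

test_that("rankAndCall sorts by |K| with MD/name tie-breaks", {
    tab <- data.frame(gmv = c("a", "b", "c"), K = c(4, -5, 1),
                      MD = c(1, 1, 1), p_h0 = c(0.9, 0.1, 0.7))
    out <- rankAndCall(tab, kThreshold = 3, mdThreshold = 0)
    expect_identical(out$gmv, c("b", "a", "c"))
    expect_identical(out$significant, c(TRUE, TRUE, FALSE))

    none <- data.frame(gmv = c("a", "b"), K = c(0, 0), MD = c(0, 0))
    expect_identical(sum(rankAndCall(none)$significant), 0L)

    ties <- data.frame(gmv = c("z", "y", "x"), K = c(2, 2, 2),
                       MD = c(0.1, 0.9, 0.1))
    expect_identical(rankAndCall(ties)$gmv, c("y", "x", "z"))

    # md threshold gates the significance call
    big <- data.frame(gmv = "a", K = 8, MD = 2)
    expect_false(rankAndCall(big, mdThreshold = 5)$significant)
    expect_true(rankAndCall(big, mdThreshold = 1)$significant)
})
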