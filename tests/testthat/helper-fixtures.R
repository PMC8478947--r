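# Shared fixtures, built in code at test time.

# tiny GMT file: two sets of sizes 3 and 5
writeTinyGMT <- function(path = tempfile(fileext = ".gmt")) {
    writeLines(c(
        "SET3\tfirst set\tG1\tG2\tG3",
        "SET5\tsecond set\tG2\tG4\tG5\tG6\tG7"), path)
    path
}

# small simulated dataset + mask + untrained model, shared across tests
smallSim <- function(seed = 7L, ...) {
    simulateModuleData(vegaSimConfig(
        nCellsPerGroup = 150L, nGenes = 200L, nModules = 5L,
        genesPerModule = 25L, overlapFraction = 0.1, seed = seed, ...))
}

smallModel <- function(sim, nFC = 1L, nHidden = 32L, seed = 5L, ...) {
    bm <- buildMask(sim$modules, rownames(sim$data), nFC = nFC,
                    minGenes = 5L)
    vegaModel(bm, nHidden = nHidden, seed = seed, ...)
}

# brute-force silhouette per its defining formula, used as the oracle
bruteSilhouette <- function(emb, labels) {
    emb <- as.matrix(emb)
    d <- as.matrix(dist(emb))
    labels <- as.character(labels)
    n <- nrow(emb)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        a <- if (length(own) > 1L) mean(d[i, setdiff(own, i)]) else 0
        b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
            mean(d[i, labels == l]), 1.0))
        s[i] <- if (length(own) > 1L) (b - a) / max(a, b) else 0
    }
    s
}

# numerical KL(q || N(0,1)) for scalar mu, sigma by quadrature
numericKL <- function(mu, sigma) {
    f <- function(x) {
        q <- dnorm(x, mu, sigma)
        lr <- dnorm(x, mu, sigma, log = TRUE) - dnorm(x, log = TRUE)
        ifelse(q > 0, q * lr, 0)
    }
    integrate(f, mu - 12 * sigma, mu + 12 * sigma,
              rel.tol = 1e-10, abs.tol = 1e-12)$value
}
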