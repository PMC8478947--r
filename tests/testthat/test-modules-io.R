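test_that("readGMT parses, deduplicates and preserves file order", {
    path <- tempfile(fileext = ".gmt")
    writeLines(c("SETA\tdesc\tG1\tG2\tG2",
                 "SETB\tother\tG3\tG4\tG5"), path)
    gmc <- readGMT(path)
    expect_s4_class(gmc, "GeneModuleCollection")
    expect_identical(names(gmc), c("SETA", "SETB"))
    expect_identical(gmc[["SETA"]], c("G1", "G2"))  # dedup forced
    expect_identical(unname(moduleSizes(gmc)), c(2L, 3L))

    two <- readGMT(writeTinyGMT())
    expect_length(two, 2L)
    expect_identical(unname(moduleSizes(two)), c(3L, 5L))
})

test_that("readGMT handles empty files and rejects malformed input", {
    empty <- tempfile(fileext = ".gmt")
    file.create(empty)
    expect_length(readGMT(empty), 0L)

    bad <- tempfile(fileext = ".gmt")
    writeLines(c("SETA\tdesc\tG1", "BROKEN\tonly-two-fields"), bad)
    expect_error(readGMT(bad), "line 2")

    dup <- tempfile(fileext = ".gmt")
    writeLines(c("SETA\td\tG1", "SETA\td\tG2"), dup)
    expect_error(readGMT(dup), "duplicate")

    expect_error(readGMT(tempfile()), "not found")
})

test_that("GMT write/read round-trips exactly", {
    gmc <- GeneModuleCollection(
        list(ALPHA = c("G1", "G9", "G4"), BETA = c("G2", "G3"),
             GAMMA = c("G5", "G6", "G7", "G8")),
        descriptions = c("a", "b", "c"))
    path <- tempfile(fileext = ".gmt")
    writeGMT(gmc, path)
    back <- readGMT(path)
    expect_identical(back@modules, gmc@modules)
    expect_identical(back@descriptions, gmc@descriptions)
})

test_that("uppercase normalization flag reconciles symbol case", {
    path <- tempfile(fileext = ".gmt")
    writeLines("seta\td\tTp53\tbrca1", path)
    expect_identical(readGMT(path, toupper = TRUE)[["seta"]],
                     c("TP53", "BRCA1"))
})

test_that("readRegulonTable groups targets by regulator, order preserved", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("TFA\tG1", "TFA\tG2", "TFB\tG1"), path)
    gmc <- readRegulonTable(path)
    expect_identical(names(gmc), c("TFA", "TFB"))
    expect_identical(gmc[["TFA"]], c("G1", "G2"))
    expect_identical(gmc[["TFB"]], "G1")

    empty <- tempfile()
    file.create(empty)
    expect_length(readRegulonTable(empty), 0L)

    onecol <- tempfile()
    writeLines(c("TFA", "TFB"), onecol)
    expect_error(readRegulonTable(onecol), "2 columns")
})

test_that("a regulator listed as its own target is retained", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("TFA\tTFA", "TFA\tG2", "TFB\tG3"), path)
    gmc <- readRegulonTable(path)
    expect_true("TFA" %in% gmc[["TFA"]])
    # round-trip through GMT keeps the self-edge
    p2 <- tempfile(fileext = ".gmt")
    writeGMT(gmc, p2)
    expect_true("TFA" %in% readGMT(p2)[["TFA"]])
})

test_that("buildMask wires module membership and appends FC columns", {
    gmc <- GeneModuleCollection(list(M = c("G1", "G2")))
    bm <- buildMask(gmc, c("G1", "G2", "G3"), minGenes = 1L)
    expect_identical(unname(bm$mask[, 1L]), c(1, 1, 0))

    # missing-module handling
    gone <- GeneModuleCollection(list(M = "G9"))
    expect_error(suppressWarnings(buildMask(gone, c("G1", "G2"),
                                            minGenes = 1L)),
                 "no gene module survives")
    both <- GeneModuleCollection(list(M = "G9", K = c("G1", "G2")))
    expect_warning(bm2 <- buildMask(both, c("G1", "G2"), minGenes = 1L),
                   "dropped")
    expect_identical(colnames(bm2$mask)[1L], "K")
    expect_identical(bm2$layout@nGMV, 1L)
})

test_that("gmv column sums equal module-times-universe intersections", {
    set.seed(42)
    genes <- sprintf("g%04d", 1:1000)
    mods <- lapply(1:50, function(i) sample(genes, 20L))
    # make some members fall outside the universe
    mods[[7L]][1:5] <- paste0("alien", 1:5)
    names(mods) <- sprintf("mod%02d", 1:50)
    gmc <- GeneModuleCollection(mods)
    bm <- buildMask(gmc, genes, nFC = 3L, minGenes = 5L)
    expect_identical(dim(bm$mask), c(1000L, 53L))
    expected <- vapply(mods, function(m) length(intersect(m, genes)), 1L)
    expect_identical(unname(colSums(bm$mask[, 1:50])),
                     as.double(unname(expected)))
    expect_true(all(bm$mask %in% c(0, 1)))
    expect_true(all(colSums(bm$mask[, 51:53]) == 1000))
    # deterministic given inputs
    bm2 <- buildMask(gmc, genes, nFC = 3L, minGenes = 5L)
    expect_identical(bm$mask, bm2$mask)
})

test_that("covariate columns are all-ones and layout tracks provenance", {
    gmc <- GeneModuleCollection(list(M = c("G1", "G2", "G3")))
    bm <- buildMask(gmc, paste0("G", 1:5), nFC = 2L,
                    covariateLevels = c("b1", "b2"), minGenes = 3L)
    expect_identical(bm$layout@nodeKinds,
                     c("gmv", "fc", "fc", "covariate", "covariate"))
    expect_true(all(bm$mask[, 2:5] == 1))
    expect_identical(latentNames(bm$layout),
                     c("M", "FC_1", "FC_2", "COV_b1", "COV_b2"))
})

test_that("more than 16 FC nodes triggers the advisory warning", {
    gmc <- GeneModuleCollection(list(M = paste0("G", 1:6)))
    expect_warning(buildMask(gmc, paste0("G", 1:20), nFC = 17L,
                             minGenes = 5L), "16")
    expect_silent(buildMask(gmc, paste0("G", 1:20), nFC = 16L,
                            minGenes = 5L))
})
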