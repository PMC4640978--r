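# Vertex-wise GLM, F-tests, effect maps and family-wise correction.

makeCohort <- function(n, nsite = 2, seed = 1) {
    set.seed(seed)
    data.frame(age = rnorm(n, 73, 6), weight = rnorm(n, 84, 13),
               height = rnorm(n, 174, 7),
               site = factor(sample(LETTERS[seq_len(nsite)], n,
                                    replace = TRUE)))
}

test_that("design assembly matches the model specifications", {
    n <- 60
    coh <- makeCohort(n)
    sc <- matrix(rnorm(n * 6), n, 6)
    X <- buildDesign(coh, sc, spec = "selected")
    # intercept + S0 + Age + S1..S5 + one site dummy = 9 columns
    expect_identical(ncol(X), 9L)
    expect_identical(colnames(X)[attr(X, "contrast")], "S0")
    # age centred
    expect_equal(mean(X[, "Age"]), 0, tolerance = 1e-10)
    # collinearity audit reported
    expect_true(is.matrix(attr(X, "correlations")))
    # exploration models swap/extend columns
    Xh <- buildDesign(coh, sc, spec = "exploration-height")
    expect_true(all(c("Hgt", "Wgt") %in% colnames(Xh)))
    expect_identical(colnames(Xh)[attr(Xh, "contrast")], "Hgt")
    # single site: dropped with a warning
    expect_warning(buildDesign(makeCohort(n, nsite = 1), sc), "site")
    # rank deficiency names the dependent columns
    cohBad <- coh; cohBad$weight <- 2 * cohBad$height
    expect_error(buildDesign(cohBad, sc, spec = "exploration-height"),
                 "rank deficient")
})

test_that("the GLM matches an independent per-vertex regression", {
    n <- 40; V <- 25
    coh <- makeCohort(n, seed = 3)
    sc <- matrix(rnorm(n * 6), n, 6)
    X <- buildDesign(coh, sc, spec = "selected")
    set.seed(4)
    Y <- matrix(rnorm(n * V, 200, 10), n, V)
    ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
    for (v in c(1, 7, 25)) {
        lmv <- lm(Y[, v] ~ X - 1)
        expect_equal(unname(ft@coef[, v]), unname(coef(lmv)),
                     tolerance = 1e-10)
        lmr <- lm(Y[, v] ~ X[, -attr(X, "contrast")] - 1)
        Fref <- ((sum(residuals(lmr)^2) - sum(residuals(lmv)^2)) / 1) /
            (sum(residuals(lmv)^2) / ft@df[2])
        expect_equal(ft@Fmap[v], Fref, tolerance = 1e-10)
    }
    # single-column F equals squared t
    tv <- summary(lm(Y[, 1] ~ X - 1))$coefficients["XS0", "t value"]
    expect_equal(ft@Fmap[1], tv^2, tolerance = 1e-8)
    # permuting subjects in both design and Y leaves the result unchanged
    perm <- sample.int(n)
    Xp <- X[perm, ]; attributes(Xp)$contrast <- attr(X, "contrast")
    ftp <- fTest(fitGlm(Xp, Y[perm, ], mesh = gridMesh),
                 contrast = attr(X, "contrast"))
    expect_equal(ftp@Fmap, ft@Fmap, tolerance = 1e-10)
    # exactly linear responses give zero residuals
    B <- matrix(rnorm(ncol(X) * V), ncol(X), V)
    ftz <- fitGlm(X, X %*% B, mesh = gridMesh)
    expect_lt(max(ftz@sigma), 1e-8)
    expect_equal(unname(ftz@coef), B, tolerance = 1e-8)
})

test_that("null F-maps follow the central F distribution", {
    n <- 50; V <- 1000
    coh <- makeCohort(n, seed = 5)
    sc <- matrix(rnorm(n * 6), n, 6)
    X <- buildDesign(coh, sc, spec = "selected")
    set.seed(6)
    Y <- matrix(rnorm(n * V), n, V)
    ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
    ks <- suppressWarnings(ks.test(ft@Fmap, pf, ft@df[1], ft@df[2]))
    expect_gt(ks$p.value, 0.01)
})

test_that("effect maps read as percent per SD", {
    n <- 60
    coh <- makeCohort(n, seed = 7)
    sc <- matrix(rnorm(n * 6), n, 6)
    sc <- scale(sc)
    X <- buildDesign(coh, sc, spec = "selected")
    V <- 40
    base <- runif(V, 150, 250)
    eff <- -6.87
    # noiseless multiplicative planted effect
    Y <- outer(sc[, 1], base * eff / 100) +
        matrix(base, n, V, byrow = TRUE)
    ft <- effectPercentMap(fTest(fitGlm(X, Y, mesh = gridMesh)))
    expect_equal(ft@effect, rep(eff, V), tolerance = 0.1)
    # beta = 0 gives 0%
    Y0 <- matrix(base, n, V, byrow = TRUE)
    ft0 <- effectPercentMap(fTest(fitGlm(X, Y0, mesh = gridMesh)))
    expect_equal(max(abs(ft0@effect)), 0, tolerance = 1e-8)
    # doubling Y leaves the percent map unchanged
    ft2 <- effectPercentMap(fTest(fitGlm(X, 2 * Y, mesh = gridMesh)))
    expect_equal(ft2@effect, ft@effect, tolerance = 1e-8)
})

test_that("planted focal signals dominate the F-map", {
    n <- 60; V <- nrow(vertices(gridMesh))
    coh <- makeCohort(n, seed = 8)
    sc <- scale(matrix(rnorm(n * 6), n, 6))
    X <- buildDesign(coh, sc, spec = "selected")
    patch <- 101:140
    set.seed(9)
    Y <- matrix(rnorm(n * V, 200, 6), n, V)
    Y[, patch] <- Y[, patch] + outer(sc[, 1], rep(25, length(patch)))
    ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
    expect_gt(min(ft@Fmap[patch]), max(ft@Fmap[-patch]))
})

test_that("permutation correction controls trivial cases", {
    n <- 40; V <- nrow(vertices(gridMesh))
    coh <- makeCohort(n, seed = 10)
    sc <- scale(matrix(rnorm(n * 6), n, 6))
    X <- buildDesign(coh, sc, spec = "selected")
    set.seed(11)
    Y <- matrix(rnorm(n * V), n, V)
    ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
    expect_error(correctedPMaps(ft, nPerm = 50L), "100")
    # strong planted effect: the patch cluster is highly significant
    patch <- 201:260
    Yp <- Y; Yp[, patch] <- Yp[, patch] + outer(sc[, 1],
                                                rep(3, length(patch)))
    ftp <- fTest(fitGlm(X, Yp, mesh = gridMesh))
    ftp <- correctedPMaps(ftp, nPerm = 400L, seed = 2)
    expect_gt(nrow(ftp@clusters), 0L)
    expect_lt(ftp@clusters$pCorrected[1], 0.01)
    # the detected cluster overlaps the planted patch
    best <- which(ftp@clusterId == ftp@clusters$id[1])
    dice <- 2 * length(intersect(best, patch)) /
        (length(best) + length(patch))
    expect_gt(dice, 0.5)
})

test_that("permutation peak correction controls the family-wise error", {
    # null simulation at reduced scale: n = 60 subjects, 500 vertices
    n <- 60; V <- nrow(vertices(gridMesh))
    reps <- 200L
    coh <- makeCohort(n, seed = 12)
    sc <- scale(matrix(rnorm(n * 6), n, 6))
    X <- buildDesign(coh, sc, spec = "selected")
    graph <- meshGraph(gridMesh)
    set.seed(13)
    hits <- 0L
    for (b in seq_len(reps)) {
        Y <- matrix(rnorm(n * V), n, V)
        ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
        ft <- correctedPMaps(ft, nPerm = 100L, seed = b, graph = graph)
        if (min(ft@peakP) < 0.05) hits <- hits + 1L
    }
    fwer <- hits / reps
    expect_gte(fwer, 0.03)
    expect_lte(fwer, 0.07)
})

test_that("the RFT approximation is sane and monotone", {
    n <- 50; V <- nrow(vertices(gridMesh))
    coh <- makeCohort(n, seed = 14)
    sc <- scale(matrix(rnorm(n * 6), n, 6))
    X <- buildDesign(coh, sc, spec = "selected")
    set.seed(15)
    Y <- matrix(rnorm(n * V), n, V)
    Y <- t(smoothSurface(t(Y), gridMesh, fwhm = 4))  # smooth null field
    ft <- fTest(fitGlm(X, Y, mesh = gridMesh))
    ft <- correctedPMaps(ft, method = "rft")
    expect_true(all(ft@peakP >= 0 & ft@peakP <= 1))
    # corrected p decreases with F
    ord <- order(ft@Fmap)
    expect_true(all(diff(ft@peakP[ord]) <= 1e-12))
    expect_identical(ft@method, "rft")
})
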