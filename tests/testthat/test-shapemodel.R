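# PCA shape model: Gram-matrix construction, projection, mode metrics.

test_that("identical shapes give a degenerate model", {
    X <- matrix(rep(as.vector(vertices(canon)), 5), nrow = 5,
                byrow = TRUE)
    sm <- suppressMessages(buildShapeModel(X, canon))
    expect_true(all(modeSD(sm) < 1e-8) || ncol(shapeModes(sm)) == 0)
    expect_true(all(abs(scores(sm)) < 1e-6))
})

test_that("a planted one-direction dataset is recovered as mode 1", {
    set.seed(13)
    dir <- rnorm(16740); dir <- dir / sqrt(sum(dir^2))
    amps <- rnorm(12, 0, 5)
    X <- t(vapply(amps, function(a)
        as.vector(vertices(canon)) + a * dir, numeric(16740)))
    sm <- suppressMessages(buildShapeModel(X, canon))
    expect_gt(abs(sum(shapeModes(sm)[, 1] * dir)), 0.999)
    expect_gt(varianceFraction(sm)[1], 0.999)
})

test_that("Gram-matrix PCA equals direct covariance eigendecomposition", {
    set.seed(17)
    n <- 5; d <- 30
    X <- matrix(rnorm(n * d), n, d)
    Xc <- scale(X, scale = FALSE)
    direct <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    # build through the same Gram route the full-size model uses
    G <- tcrossprod(Xc) / (n - 1)
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values[seq_len(n - 1)]
    expect_equal(lam, direct$values[seq_len(n - 1)], tolerance = 1e-8)
})

test_that("projection and reconstruction are exact and standardisable", {
    p <- malePreset(n = 30)
    truth <- plantedShapeModel(p, canon)
    set.seed(19)
    S <- matrix(rnorm(30 * 10), 30, 10)
    X <- t(apply(S, 1, function(s)
        reconstructShape(s, truth, standardized = TRUE)))
    sm <- buildShapeModel(X, canon)
    # project the mean: all zeros
    expect_equal(max(abs(projectShape(shapeMean(sm), sm))), 0,
                 tolerance = 1e-8)
    # project a training shape then reconstruct with all modes: exact
    s1 <- projectShape(X[3, ], sm)
    expect_equal(reconstructShape(s1, sm), X[3, ], tolerance = 1e-8)
    # independent loop-based dot product matches the operation
    byHand <- vapply(seq_len(ncol(shapeModes(sm))), function(j)
        sum((X[3, ] - shapeMean(sm)) * shapeModes(sm)[, j]), 0)
    expect_equal(s1, byHand, tolerance = 1e-10)
    # standardised scores have unit variance per mode
    sc <- scores(sm, standardized = TRUE)
    expect_equal(apply(sc, 2L, function(x)
        sum(x^2) / (nrow(sc) - 1)), rep(1, ncol(sc)), tolerance = 1e-8)
    # PCA decorrelation: mode-1 scores uncorrelated with the others
    cors <- cor(sc)[1, -1]
    expect_lt(max(abs(cors)), 1e-8)
    # sign convention: largest-magnitude component positive
    for (j in 1:3) {
        i <- which.max(abs(shapeModes(sm)[, j]))
        expect_gt(shapeModes(sm)[i, j], 0)
    }
})

test_that("variance fractions of a planted cohort are recovered", {
    p <- malePreset(n = 308)
    truth <- plantedShapeModel(p, canon)
    set.seed(23)
    S <- matrix(rnorm(308 * 10), 308, 10)
    X <- t(apply(S, 1, function(s)
        reconstructShape(s, truth, standardized = TRUE)))
    sm <- buildShapeModel(X, canon)
    vf <- 100 * varianceFraction(sm)
    expect_equal(vf[1], 58, tolerance = 3)
    expect_equal(vf[2], 15, tolerance = 3)
    expect_equal(vf[3], 6, tolerance = 3)
})

test_that("mode extent change measures anisotropic size correctly", {
    p <- malePreset(n = 40)
    truth <- plantedShapeModel(p, canon)
    set.seed(29)
    S <- matrix(rnorm(40 * 10), 40, 10)
    X <- t(apply(S, 1, function(s)
        reconstructShape(s, truth, standardized = TRUE)))
    sm <- orientMode(buildShapeModel(X, canon), 1, "proximalDistal")
    pd <- modeExtentChange(sm, 1, "proximalDistal")
    expect_equal(pd, 7, tolerance = 1)
    expect_equal(modeExtentChange(sm, 1, "medialLateral"), 4,
                 tolerance = 1)
    # orientation makes +1 SD enlarge the femur
    expect_gt(pd, 0)
    # unlabelled axis errors; zero-variance mode gives 0
    expect_error(modeExtentChange(sm, 1, "bogus"), "not labelled")
    smz <- sm; smz@sdev[3] <- 0
    expect_identical(modeExtentChange(smz, 3, "proximalDistal"), 0)
})

test_that("mode-extreme meshes export symmetrically and round-trip", {
    p <- malePreset(n = 30)
    truth <- plantedShapeModel(p, canon)
    out <- exportModeMeshes(truth, mode = 1, k = 3,
                            dir = file.path(tempdir(), "modes"))
    mid <- (vertices(out$plus) + vertices(out$minus)) / 2
    expect_equal(mid, vertices(canon), tolerance = 1e-8)
    rt <- readPLY(out$files[1])
    expect_equal(vertices(rt), vertices(out$plus), tolerance = 1e-4)
    expect_identical(faces(rt), faces(out$plus))
    # k = 0 is the identity
    out0 <- exportModeMeshes(truth, mode = 1, k = 0)
    expect_equal(vertices(out0$plus), vertices(canon), tolerance = 1e-10)
})
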