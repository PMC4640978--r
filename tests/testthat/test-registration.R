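# Rigid + nonrigid registration, data transfer, surface smoothing.

test_that("rigid self-registration recovers known transforms", {
    # identity
    r0 <- rigidAlign(canon, canon)
    expect_lt(max(abs(r0$R - diag(3))), 1e-6)
    expect_lt(max(abs(r0$t)), 1e-4)
    # randomised poses: transform recovered, residual tiny
    set.seed(5)
    for (k in 1:5) {
        ang <- runif(3, -0.3, 0.3); tr <- runif(3, -15, 15)
        R <- boneSPM:::rotZ(ang[3]) %*% boneSPM:::rotY(ang[2]) %*%
            boneSPM:::rotX(ang[1])
        V <- sweep(vertices(canon) %*% t(R), 2L, tr, "+")
        tgt <- new("FemurMesh", vertices = V, faces = faces(canon),
                   normals = normals(canon) %*% t(R),
                   axes = canon@axes, metadata = canon@metadata)
        r <- rigidAlign(canon, tgt)
        expect_lt(r$residual, 0.1)
        expect_lt(max(abs(r$R - R)), 1e-2)
    }
})

test_that("nonrigid registration round-trips planted deformations", {
    p <- malePreset(n = 24)
    sm <- plantedShapeModel(p, canon)
    coh <- generateCohort(p, seed = 9)
    msN <- subjectMeshes(coh, sm, seed = 9, pose = FALSE, preset = p)
    msP <- subjectMeshes(coh, sm, seed = 9, pose = TRUE, preset = p)
    corrs <- lapply(1:6, function(i)
        suppressWarnings(nonrigidRegister(canon, msP[[i]])))
    expect_identical(length(as.vector(corrs[[1]]@deformed)), 16740L)
    # quality control passes for the bulk of subjects ...
    okQC <- vapply(corrs, function(cc)
        mean(cc@residual) <= 0.5 && cc@roughness <= 0.2, logical(1))
    expect_gte(sum(okQC), 4L)
    # ... and those registrations round-trip below 0.1 mm on average
    errs <- vapply(which(okQC), function(i)
        mean(sqrt(rowSums((corrs[[i]]@deformed -
                           msN[[i]]@vertices)^2))), 0)
    expect_lt(mean(errs), 0.1)
    # size signal preserved: bounding extents within 1% of the target's
    corr <- suppressWarnings(nonrigidRegister(canon, msN[[1]]))
    for (ax in c("proximalDistal", "medialLateral"))
        expect_equal(boundingExtent(corr@deformed, ax, canon),
                     boundingExtent(msN[[1]], ax, canon),
                     tolerance = 0.01 *
                         boundingExtent(msN[[1]], ax, canon))
})

test_that("registering the canonical to itself is the identity", {
    corr <- nonrigidRegister(canon, canon)
    expect_lt(mean(sqrt(rowSums((corr@deformed -
                                 vertices(canon))^2))), 1e-8)
})

test_that("transferred fields behave under barycentric interpolation", {
    p <- malePreset(n = 24)
    sm <- plantedShapeModel(p, canon)
    tgt <- deformMesh(canon, c(0.8, -0.5, 0.3), sm)
    corr <- suppressWarnings(nonrigidRegister(canon, tgt))
    # constant field -> constant output
    out <- transferData(rep(7, 5580), corr, faces(tgt))
    expect_equal(as.vector(out), rep(7, 5580))
    # linear-in-space field is reproduced exactly at the matched points
    lin <- as.vector(vertices(tgt) %*% c(0.3, -0.2, 0.5)) + 4
    outL <- transferData(lin, corr, faces(tgt))
    matched <- corr@bary[, 1] * lin[faces(tgt)[corr@triangle, 1]] +
        corr@bary[, 2] * lin[faces(tgt)[corr@triangle, 2]] +
        corr@bary[, 3] * lin[faces(tgt)[corr@triangle, 3]]
    expect_equal(as.vector(outL), as.vector(matched), tolerance = 1e-12)
    # transferred planted field correlates > 0.99 with ground truth
    fld <- generateTrueField(list(trueS0 = 1, age = 73.5,
                                  site = "Birmingham"),
                             malePreset(field = list(noiseSdLogCth = 0,
                                                     noiseSdLogCbmd = 0)),
                             mesh = canon)
    outF <- transferData(cmsd(fld), corr, faces(tgt))
    expect_gt(cor(as.vector(outF), cmsd(fld)), 0.99)
    # flagged source vertices propagate missingness with renormalisation
    v <- cmsd(fld); v[1:200] <- NA
    outM <- suppressWarnings(transferData(v, corr, faces(tgt)))
    expect_true(anyNA(outM) || attr(outM, "missing") == 0)
})

test_that("identity correspondence returns the field unchanged", {
    corr <- nonrigidRegister(canon, canon)
    x <- rnorm(5580)
    out <- transferData(x, corr, faces(canon))
    expect_equal(as.vector(out), x, tolerance = 1e-6)
})

test_that("surface smoothing is calibrated, conservative and contractive", {
    x <- rnorm(5580)
    # fwhm = 0 is the identity
    expect_identical(smoothSurface(x, canon, fwhm = 0), x)
    # constant fields are unchanged for any fwhm
    expect_equal(smoothSurface(rep(3, 5580), canon, fwhm = 12),
                 rep(3, 5580), tolerance = 1e-9)
    # smoothing is a contraction in variance
    expect_lt(var(smoothSurface(x, canon, fwhm = 8)), var(x))
    # a delta spreads with mass conserved to < 1% (interior vertex)
    d <- numeric(5580); d[2500] <- 1
    sm <- smoothSurface(d, canon, fwhm = 8)
    expect_equal(sum(sm), 1, tolerance = 0.01)
    expect_lt(max(sm), 0.2)
    # missing values stay missing and are excluded from averages
    xm <- x; xm[100:110] <- NA
    smm <- smoothSurface(xm, canon, fwhm = 6)
    expect_true(all(is.na(smm[100:110])))
    expect_false(anyNA(smm[-(100:110)]))
})
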