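# The synthetic-data generator: cohorts, planted modes, fields, profiles.

test_that("cohorts are deterministic and match the preset moments", {
    p <- malePreset()
    c1 <- generateCohort(p, seed = 11)
    c2 <- generateCohort(p, seed = 11)
    expect_identical(c1, c2)
    c3 <- generateCohort(p, seed = 12)
    expect_false(identical(c1$age, c3$age))
    expect_identical(nrow(c1), 308L)
    # sample moments near the preset (printed) moments
    expect_equal(mean(c1$age), 73.5, tolerance = 0.02)
    expect_equal(sd(c1$age), 5.7, tolerance = 0.1)
    expect_equal(mean(c1$height), 174.3, tolerance = 0.01)
    expect_true(all(c1$age >= 65 & c1$age <= 91))
    expect_true(all(c1$weight >= 56 & c1$weight <= 125))
    expect_true(all(levels(c1$site) %in% p$sites))
})

test_that("the copula realises the planted covariate correlations", {
    coh <- generateCohort(malePreset(n = 600), seed = 21)
    expect_equal(cor(coh$height, coh$trueS0), 0.64, tolerance = 0.08)
    expect_equal(cor(coh$weight, coh$trueS0), 0.42, tolerance = 0.10)
    expect_lt(abs(cor(coh$age, coh$trueS0)), 0.12)
})

test_that("infeasible correlation targets are rejected with a diagnostic", {
    p <- malePreset(corr = c(height = 0.95, weight = -0.9, age = 0.9,
                             heightWeight = 0.5))
    expect_error(generateCohort(p, seed = 1), "positive-definite")
})

test_that("deformMesh is the linear mean-plus-modes construction", {
    sm <- plantedShapeModel(malePreset(), canon)
    # S = 0 is the mean shape exactly
    m0 <- deformMesh(canon, 0, sm)
    expect_equal(vertices(m0), vertices(canon))
    expect_identical(faces(m0), faces(canon))
    # +1 SD of size enlarges proximal-distal extent by about 7%
    plus <- deformMesh(canon, 1, sm)
    expect_equal(boundingExtent(plus, "proximalDistal", canon) /
                 boundingExtent(canon, "proximalDistal"),
                 1.07, tolerance = 0.003)
    # and the transverse extents by about 4%
    expect_equal(boundingExtent(plus, "medialLateral", canon) /
                 boundingExtent(canon, "medialLateral"),
                 1.04, tolerance = 0.005)
    # deform then project back recovers the coefficients (orthonormality)
    S <- c(0.7, -1.2, 0.5, 0.3, -0.6)
    m <- deformMesh(canon, S, sm)
    Srec <- projectShape(m, sm, standardized = TRUE)
    expect_equal(Srec[1:5], S, tolerance = 1e-10)
    expect_equal(max(abs(crossprod(shapeModes(sm)) -
                         diag(ncol(shapeModes(sm))))), 0,
                 tolerance = 1e-8)
})

test_that("planted mode variance structure matches the preset", {
    p <- malePreset()
    sm <- plantedShapeModel(p, canon)
    expect_equal(varianceFraction(sm), p$modeVariances,
                 tolerance = 1e-10)
    expect_equal(modeSD(sm)^2 / sum(modeSD(sm)^2), p$modeVariances,
                 tolerance = 1e-10)
})

test_that("true fields carry the planted multiplicative patch effect", {
    p <- malePreset(field = list(noiseSdLogCth = 0, noiseSdLogCbmd = 0))
    region <- plantedRegion(canon)
    base <- generateTrueField(list(trueS0 = 0, age = 73.5,
                                   site = "Birmingham"), p, mesh = canon)
    f1 <- generateTrueField(list(trueS0 = 1, age = 73.5,
                                 site = "Birmingham"), p, mesh = canon)
    # inside the patch: CMSD scaled by exactly 1 + effect/100
    expect_equal(mean(cmsd(f1)[region]) / mean(cmsd(base)[region]),
                 1 - 6.87 / 100, tolerance = 1e-12)
    # outside: baseline untouched
    out <- setdiff(seq_len(5580), region)
    expect_equal(cmsd(f1)[out], cmsd(base)[out], tolerance = 1e-12)
    # log-CMSD difference per unit S0 equals log(1 + effect) in the patch
    expect_equal(mean(log(cmsd(f1)[region]) - log(cmsd(base)[region])),
                 log(1 - 0.0687), tolerance = 1e-12)
    # product identity holds everywhere
    expect_equal(cmsd(f1), cth(f1) * cbmd(f1), tolerance = 1e-12)
    # effect driving CTh below the floor is clipped with a warning
    pBad <- malePreset(patchEffect = -40,
                       field = list(noiseSdLogCth = 0,
                                    noiseSdLogCbmd = 0))
    expect_warning(generateTrueField(list(trueS0 = 3, age = 73.5,
                                          site = "Birmingham"),
                                     pBad, mesh = canon), "clipped")
})

test_that("field noise is seeded and reproducible", {
    p <- malePreset()
    s <- list(trueS0 = 0.5, age = 70, site = "Portland")
    f1 <- generateTrueField(s, p, mesh = canon, seed = 3)
    f2 <- generateTrueField(s, p, mesh = canon, seed = 3)
    f3 <- generateTrueField(s, p, mesh = canon, seed = 4)
    expect_identical(cth(f1), cth(f2))
    expect_false(identical(cth(f1), cth(f3)))
})

test_that("synthesised profiles follow the blurred three-level model", {
    img <- list(sigma = 0.75, noiseSD = 25, spacing = 0.5, extent = 15)
    thick <- new("CorticalMap", cth = rep(0.5, 5580),
                 cbmd = rep(1200, 5580), cmsd = rep(600, 5580),
                 flag = rep(FALSE, 5580), mesh = canon)
    # near-zero blur, zero noise: plateau equals the true CBMD
    img0 <- list(sigma = 0.01, noiseSD = 0, spacing = 0.5, extent = 15)
    pr <- synthesizeProfiles(thick, img0, seed = NULL, vertices = 1:3)
    mid <- pr@positions > 1 & pr@positions < 4
    expect_equal(unname(pr@values[1, mid]),
                 rep(1200, sum(mid)), tolerance = 1e-6)
    # thin cortex under real blur: peak strictly below CBMD, matching the
    # numeric convolution oracle
    thin <- new("CorticalMap", cth = rep(0.15, 5580),
                cbmd = rep(1200, 5580), cmsd = rep(180, 5580),
                flag = rep(FALSE, 5580), mesh = canon)
    prT <- synthesizeProfiles(thin, modifyList(img, list(noiseSD = 0)),
                              seed = NULL, vertices = 1L)
    oracle <- convOracle(list(y0 = 30, y1 = 1200, y2 = 150, x0 = 0,
                              x1 = 1.5, sigma = 0.75), prT@positions)
    expect_lt(max(prT@values[1, ]), 1200)
    expect_equal(unname(prT@values[1, ]), oracle, tolerance = 0.5)
    # doubling sigma never increases the peak
    peaks <- vapply(c(0.4, 0.8, 1.6), function(sg) {
        pp <- synthesizeProfiles(thin, modifyList(img,
                  list(sigma = sg, noiseSD = 0)), seed = NULL,
                  vertices = 1L)
        max(pp@values)
    }, 0)
    expect_true(all(diff(peaks) <= 1e-9))
    # blur conserves mass: with zero outside/trabecular densities the
    # profile integral equals CTh x CBMD regardless of sigma
    for (sg in c(0.4, 1.2)) {
        pp <- synthesizeProfiles(thin, modifyList(img,
                  list(sigma = sg, noiseSD = 0)), seed = NULL,
                  vertices = 1L, outside = 0, trabecular = 0)
        area <- sum(pp@values[1, ]) * img$spacing / 10  # mm -> cm
        expect_equal(area, 0.15 * 1200, tolerance = 0.15 * 1200 * 0.002)
    }
    # profile synthesis is deterministic given the seed
    a <- synthesizeProfiles(thick, img, seed = 5, vertices = 1:4)
    b <- synthesizeProfiles(thick, img, seed = 5, vertices = 1:4)
    expect_identical(a@values, b@values)
    # extent too small for cortex + 4 sigma is rejected
    expect_error(synthesizeProfiles(thick,
        list(sigma = 3, noiseSD = 0, spacing = 0.5, extent = 10),
        vertices = 1:3), "extent")
})

test_that("phantom volume agrees with direct profile synthesis", {
    img <- list(sigma = 0.75, noiseSD = 0, spacing = 0.5, extent = 15)
    fld <- generateTrueField(list(trueS0 = 0, age = 73.5,
                                  site = "Birmingham"),
                             malePreset(field = list(noiseSdLogCth = 0,
                                                     noiseSdLogCbmd = 0)),
                             mesh = canon)
    ph <- suppressWarnings(rasterizePhantomVolume(canon, fld, img,
                                                  voxel = 1.2))
    # shaft vertices (low curvature) for the comparison
    md <- canon@metadata
    shaft <- which(md$ringParameter[md$ring] < 0.35)
    vsub <- shaft[round(seq(1, length(shaft), length.out = 15))]
    pv <- sampleVolumeProfiles(ph, canon, img, vertices = vsub)
    pd <- synthesizeProfiles(fld, img, seed = NULL, vertices = vsub)
    dif <- abs(pv@values - pd@values)
    # stated tolerance: voxelisation + trilinear interpolation at 1.2 mm
    # voxels against an analytic profile
    expect_lt(mean(dif), 25)
    expect_gt(cor(as.vector(pv@values), as.vector(pd@values)), 0.98)
    # an empty field gives a zero volume
    zero <- new("CorticalMap", cth = rep(0.1, 5580),
                cbmd = rep(0, 5580), cmsd = rep(0, 5580),
                flag = rep(FALSE, 5580), mesh = canon)
    phz <- suppressWarnings(rasterizePhantomVolume(canon, zero, img,
                                                   voxel = 2.5,
                                                   outside = 0,
                                                   trabecular = 0))
    expect_equal(max(abs(phz$volume)), 0)
})
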