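# Cortical bone mapping: model evaluation, fitting, global constraint,
# sigma-discrepancy adjustment.

pos <- seq(-15, 15, 0.5)

test_that("modelProfile matches its limits and a numeric convolution", {
    # sigma -> 0+: exact step function
    y <- modelProfile(list(y0 = 30, y1 = 1200, y2 = 150, x0 = 0,
                           x1 = 2, sigma = 1e-6), pos)
    expect_equal(y[pos < -0.01], rep(30, sum(pos < -0.01)))
    expect_equal(y[pos > 0.01 & pos < 1.99],
                 rep(1200, sum(pos > 0.01 & pos < 1.99)))
    # far inside: value tends to the trabecular level
    expect_equal(modelProfile(list(y0 = 30, y1 = 1200, y2 = 150, x0 = 0,
                                   x1 = 2, sigma = 0.75), 14), 150,
                 tolerance = 1e-6)
    # arbitrary fit vs numeric convolution of the unblurred step
    fit <- list(y0 = 45, y1 = 1130, y2 = 180, x0 = -0.7, x1 = 1.9,
                sigma = 0.9)
    oracle <- convOracle(fit, pos, dx = 0.001)
    dynRange <- fit$y1 - fit$y0
    expect_lt(max(abs(modelProfile(fit, pos) - oracle)) / dynRange,
              5e-5)
})

test_that("noiseless thick-cortex profiles are recovered to < 1%", {
    truth <- list(y0 = 30, y1 = 1150, y2 = 140, x0 = -0.3, x1 = 2.7,
                  sigma = 0.8)
    f <- fitProfile(pos, modelProfile(truth, pos))
    expect_true(f@converged)
    expect_equal(f@y1, truth$y1, tolerance = 0.01 * truth$y1)
    expect_equal(f@x1 - f@x0, 3.0, tolerance = 0.03)
    expect_equal(f@sigma, 0.8, tolerance = 0.01)
    # multi-start agreement: unconstrained thick fit is unique
    f2 <- fitProfile(pos, modelProfile(truth, pos))
    expect_equal(f@x0, f2@x0, tolerance = 1e-6)
})

test_that("the thin-cortex thickness-density ambiguity is real", {
    yThin <- modelProfile(list(y0 = 30, y1 = 1200, y2 = 150, x0 = 0,
                               x1 = 1, sigma = 0.75), pos)
    fTrue <- fitProfile(pos, yThin, y1 = 1200)
    fLow <- fitProfile(pos, yThin, y1 = 0.8 * 1200)
    # both parameterisations fit below the noise floor (25 mg/cm^3)
    expect_lt(fTrue@residual, 25)
    expect_lt(fLow@residual, 25)
    # but the fixed-density fits disagree on thickness...
    expect_gt(fLow@x1 - fLow@x0, fTrue@x1 - fTrue@x0)
    # ...while the CMSD products agree closely (the robust quantity)
    cmsdTrue <- (fTrue@x1 - fTrue@x0) / 10 * 1200
    cmsdLow <- (fLow@x1 - fLow@x0) / 10 * 960
    expect_equal(cmsdLow, cmsdTrue, tolerance = 0.05 * cmsdTrue)
})

test_that("degenerate profiles are flagged, not fitted", {
    f <- fitProfile(pos, rep(100, length(pos)))
    expect_false(f@converged)
})

test_that("estimateGlobal recovers known phantom values", {
    img <- list(sigma = 0.75, noiseSD = 25, spacing = 0.5, extent = 15)
    set.seed(31)
    n <- 150
    # mostly thick cortices: the resolvable-subset path
    cthTrue <- runif(n, 3.2, 5)
    fld <- new("CorticalMap",
               cth = c(cthTrue / 10, rep(0.2, 5580 - n)),
               cbmd = rep(1200, 5580),
               cmsd = c(cthTrue / 10, rep(0.2, 5580 - n)) * 1200,
               flag = rep(FALSE, 5580), mesh = canon)
    pr <- synthesizeProfiles(fld, img, seed = 31, vertices = 1:n)
    gl <- estimateGlobal(fitProfileStack(pr))
    expect_false(gl$fallback)
    expect_equal(gl$cbmd, 1200, tolerance = 0.02 * 1200)
    expect_equal(gl$sigma, 0.75, tolerance = 0.08)
    # all-thin phantom exercises the fallback with a warning
    fldThin <- new("CorticalMap",
                   cth = c(rep(0.12, n), rep(0.2, 5580 - n)),
                   cbmd = rep(1200, 5580),
                   cmsd = c(rep(0.12, n), rep(0.2, 5580 - n)) * 1200,
                   flag = rep(FALSE, 5580), mesh = canon)
    prT <- synthesizeProfiles(fldThin, img, seed = 32, vertices = 1:n)
    expect_warning(glT <- estimateGlobal(fitProfileStack(prT)),
                   "falling back")
    expect_true(glT$fallback)
    # noise-free uniform-sigma phantom: sigma recovered exactly
    pr0 <- synthesizeProfiles(fld, modifyList(img, list(noiseSD = 0)),
                              seed = NULL, vertices = 1:60)
    gl0 <- estimateGlobal(fitProfileStack(pr0))
    expect_equal(gl0$sigma, 0.75, tolerance = 1e-3)
    # too few accepted fits is a hard error
    expect_error(estimateGlobal(fitProfileStack(pr0, vertices = 1:10)),
                 "accepted")
})

test_that("the sigma-discrepancy adjustment conserves CMSD exactly", {
    img <- list(sigma = 0.75, noiseSD = 25, spacing = 0.5, extent = 15)
    set.seed(41)
    n <- 120
    cthTrue <- runif(n, 1, 3)
    fld <- new("CorticalMap",
               cth = c(cthTrue / 10, rep(0.2, 5580 - n)),
               cbmd = rep(1100, 5580),
               cmsd = c(cthTrue / 10, rep(0.2, 5580 - n)) * 1100,
               flag = rep(FALSE, 5580), mesh = canon)
    pr <- synthesizeProfiles(fld, img, seed = 41, vertices = 1:n)
    gl <- list(cbmd = 1100, sigma = 0.75)
    # capture pre-adjustment quantities by refitting with y1 fixed
    fits <- fitProfileStack(pr, y1 = gl$cbmd)
    mp <- constrainedMap(pr, gl, canon, vertices = 1:n)
    okf <- which(fits$converged)
    pre <- (fits$x1 - fits$x0)[okf] / 10 * gl$cbmd
    expect_equal(mp@cmsd[fits$vertex[okf]], pre, tolerance = 1e-9)
    # CMSD column always equals the product
    ok <- !mp@flag
    expect_equal(mp@cmsd[ok], mp@cth[ok] * mp@cbmd[ok],
                 tolerance = 1e-9)
    # vertices with local sigma <= global keep the global density
    noAdj <- okf[fits$sigma[okf] <= gl$sigma]
    expect_equal(unique(mp@cbmd[fits$vertex[noAdj]]), gl$cbmd)
    # vertices with excess blur get g(r) = r attribution
    adj <- okf[fits$sigma[okf] > gl$sigma]
    expect_equal(mp@cbmd[fits$vertex[adj]],
                 gl$cbmd * gl$sigma / fits$sigma[adj], tolerance = 1e-9)
})

test_that("densities scale linearly and thickness is unit-invariant", {
    truth <- list(y0 = 30, y1 = 1150, y2 = 140, x0 = 0, x1 = 2.8,
                  sigma = 0.8)
    y <- modelProfile(truth, pos)
    f1 <- fitProfile(pos, y)
    f2 <- fitProfile(pos, 1.5 * y)
    expect_equal(f2@y1, 1.5 * f1@y1, tolerance = 1e-3 * f1@y1)
    expect_equal(f2@x1 - f2@x0, f1@x1 - f1@x0, tolerance = 1e-3)
})

test_that("mapCohort handles identical subjects and coverage exclusion", {
    img <- list(sigma = 0.75, noiseSD = 10, spacing = 0.5, extent = 15)
    n <- 90
    cthv <- c(runif(n, 2, 4.5) / 10, rep(0.2, 5580 - n))
    fld <- new("CorticalMap", cth = cthv, cbmd = rep(1150, 5580),
               cmsd = cthv * 1150, flag = rep(FALSE, 5580), mesh = canon)
    pr <- synthesizeProfiles(fld, img, seed = 51, vertices = 1:n)
    out <- suppressWarnings(mapCohort(list(pr, pr), canon,
                                      globalSubsample = n,
                                      vertices = 1:n))
    expect_length(out$maps, 2L)
    expect_identical(out$maps[[1]]@cth, out$maps[[2]]@cth)
    expect_length(out$excluded, 0L)
})

test_that("CMSD is more accurately estimable than CBMD for thin cortices", {
    # spatially varying density: the regime where the thin-cortex
    # thickness-density ambiguity actually bites per-vertex CBMD while
    # the product stays estimable
    img <- list(sigma = 0.75, noiseSD = 25, spacing = 0.5, extent = 15)
    set.seed(61)
    n <- 250
    cthTrue <- runif(n, 1, 2.8)        # all below the 4-sigma limit
    cbmdTrue <- runif(n, 950, 1350)
    fld <- new("CorticalMap",
               cth = c(cthTrue / 10, rep(0.2, 5580 - n)),
               cbmd = c(cbmdTrue, rep(1100, 5580 - n)),
               cmsd = c(cthTrue / 10 * cbmdTrue,
                        rep(0.2 * 1100, 5580 - n)),
               flag = rep(FALSE, 5580), mesh = canon)
    pr <- synthesizeProfiles(fld, img, seed = 61, vertices = 1:n)
    gl <- suppressWarnings(estimateGlobal(fitProfileStack(pr)))
    mp <- constrainedMap(pr, gl, canon, vertices = 1:n)
    ok <- which(!mp@flag[1:n])
    relRms <- function(est, tru)
        sqrt(mean(((est - tru) / tru)^2))
    cmsdErr <- relRms(mp@cmsd[ok], (cthTrue / 10 * cbmdTrue)[ok])
    cbmdErr <- relRms(mp@cbmd[ok], cbmdTrue[ok])
    expect_lt(cmsdErr, cbmdErr)
})
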