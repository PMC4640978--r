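# Shared fixtures, built once per test run.

canon <- canonicalFemur()

# small flat-grid mesh for reduced-scale statistical experiments
gridMesh <- local({
    nx <- 25L; ny <- 20L
    xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    V <- cbind(xy$x, xy$y, 0)
    F1 <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3L)
    k <- 1L
    for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
        a <- (j - 1L) * nx + i
        F1[k, ] <- c(a, a + 1L, a + nx + 1L)
        F1[k + 1L, ] <- c(a, a + nx + 1L, a + nx)
        k <- k + 2L
    }
    new("FemurMesh", vertices = V, faces = F1,
        normals = matrix(rep(c(0, 0, 1), each = nrow(V)), ncol = 3),
        axes = list(), metadata = list())
})

# numerical convolution oracle for the blurred-cortex model: adaptive
# quadrature of the step profile against the Gaussian kernel, split at
# the step discontinuities (independent of the closed form under test)
convOracle <- function(fit, positions, dx = NULL) {
    kern <- function(u, x) dnorm((x - u) / fit$sigma) / fit$sigma
    vapply(positions, function(x) {
        lo <- x - 9 * fit$sigma; hi <- x + 9 * fit$sigma
        segs <- sort(unique(pmin(pmax(c(lo, fit$x0, fit$x1, hi), lo),
                                 hi)))
        lvls <- c(fit$y0, fit$y1, fit$y2)
        tot <- 0
        for (k in seq_len(length(segs) - 1L)) {
            mid <- (segs[k] + segs[k + 1L]) / 2
            lev <- if (mid < fit$x0) fit$y0 else
                if (mid < fit$x1) fit$y1 else fit$y2
            tot <- tot + lev * integrate(kern, segs[k], segs[k + 1L],
                                         x = x, rel.tol = 1e-10)$value
        }
        tot
    }, 0)
}

# cached moderate-size registered male run shared across tests
.testCache <- new.env(parent = emptyenv())
smallMaleRun <- function() {
    if (is.null(.testCache$run))
        .testCache$run <- suppressMessages(runPipeline(
            runConfig(preset = "male", n = 40, seed = 7)))
    .testCache$run
}
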