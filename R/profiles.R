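# CT-style intensity-profile synthesis and the blurred three-level model.

#' The blurred three-level cortex model
#'
#' Evaluates the density profile of a cortex modelled as a three-level
#' step function -- outside density \code{y0}, cortical density \code{y1},
#' trabecular density \code{y2} -- convolved with a Gaussian point-spread
#' function of standard deviation \code{sigma}, analytically via the
#' Gaussian cumulative function:
#' \deqn{y(x) = y_0 + (y_1 - y_0)\Phi((x - x_0)/\sigma)
#'            + (y_2 - y_1)\Phi((x - x_1)/\sigma).}
#'
#' @param fit a \code{\linkS4class{CorticalFit}}, or a named list/vector
#'   with \code{y0, y1, y2, x0, x1, sigma}.
#' @param positions mm along the outward normal.
#' @return Densities (mg/cm^3) at \code{positions}.
#' @examples
#' x <- seq(-10, 10, 0.5)
#' y <- modelProfile(list(y0 = 30, y1 = 1200, y2 = 150,
#'                        x0 = 0, x1 = 2, sigma = 0.75), x)
#' @export
modelProfile <- function(fit, positions) {
    if (is(fit, "CorticalFit"))
        fit <- list(y0 = fit@y0, y1 = fit@y1, y2 = fit@y2,
                    x0 = fit@x0, x1 = fit@x1, sigma = fit@sigma)
    with(fit, y0 + (y1 - y0) * pnorm((positions - x0) / sigma) +
              (y2 - y1) * pnorm((positions - x1) / sigma))
}

#' Synthesise CT-style intensity profiles for a cortical field
#'
#' For every vertex, builds the three-level step profile implied by the
#' field (outside density, cortical density = true CBMD over a width equal
#' to the true CTh, then trabecular density), convolves it with a Gaussian
#' of the preset blur, samples it on the preset grid and adds Gaussian
#' noise.  Deterministic given the seed.
#'
#' @param field a \code{\linkS4class{CorticalMap}} carrying true values.
#' @param imaging list with \code{sigma} (mm), \code{noiseSD} (mg/cm^3),
#'   \code{spacing} (mm) and \code{extent} (mm, half-window).
#' @param seed integer seed (\code{NULL} for no noise regardless of
#'   \code{noiseSD}).
#' @param outside,trabecular densities (mg/cm^3) outside the bone and in
#'   the trabecular compartment.
#' @param vertices optional integer subset of vertices.
#' @return An \code{\linkS4class{IntensityProfiles}} object.
#' @export
synthesizeProfiles <- function(field, imaging, seed = NULL,
                               outside = 30, trabecular = 150,
                               vertices = NULL) {
    stopifnot(imaging$sigma > 0, imaging$spacing > 0)
    pos <- seq(-imaging$extent, imaging$extent, by = imaging$spacing)
    idx <- if (is.null(vertices)) seq_along(field@cth) else vertices
    widths <- field@cth[idx] * 10          # cm -> mm
    if (any(imaging$extent < widths + 4 * imaging$sigma))
        stop("profile extent smaller than cortex width + 4 sigma at ",
             sum(imaging$extent < widths + 4 * imaging$sigma), " vertices")
    n <- length(idx)
    vals <- matrix(0, n, length(pos))
    y1 <- field@cbmd[idx]
    phi0 <- pnorm(outer(rep(1, n), pos), 0, imaging$sigma)
    # vectorised: y = y0 + (y1-y0) Phi(x/s) + (y2-y1) Phi((x-w)/s)
    phi1 <- pnorm(outer(-widths, pos, function(w, x) x + w) /
                  imaging$sigma)
    vals <- outside + (y1 - outside) * phi0 + (trabecular - y1) * phi1
    if (!is.null(seed) && imaging$noiseSD > 0) {
        set.seed(childSeed(seed, 4L))
        vals <- vals + matrix(rnorm(length(vals), 0, imaging$noiseSD),
                              nrow = n)
    }
    imaging$vertexIds <- idx
    new("IntensityProfiles", positions = pos, values = vals,
        imaging = imaging)
}

#' Rasterise a cortical-shell phantom volume
#'
#' Voxelises the cortical shell implied by a mesh and field -- each voxel
#' takes the unblurred three-level density given its signed distance along
#' the nearest vertex's normal -- and then applies a separable Gaussian
#' blur of the imaging preset's sigma.  An integration fixture: profiles
#' resampled from this volume should agree with
#' \code{\link{synthesizeProfiles}} up to interpolation and curvature
#' error.
#'
#' @param mesh a \code{FemurMesh}.
#' @param field a \code{CorticalMap} of true values on that mesh.
#' @param imaging imaging preset list (see
#'   \code{\link{synthesizeProfiles}}).
#' @param voxel voxel size in mm.
#' @param pad padding around the bounding box in mm.
#' @param outside,trabecular compartment densities (mg/cm^3).
#' @return List with \code{volume} (3D array), \code{origin} (mm) and
#'   \code{voxel} (mm).
#' @export
rasterizePhantomVolume <- function(mesh, field, imaging, voxel = 1.5,
                                   pad = 6, outside = 30,
                                   trabecular = 150) {
    if (voxel > imaging$sigma)
        warning("voxel size exceeds blur sigma; blur is under-resolved")
    bb <- apply(mesh@vertices, 2L, range)
    origin <- bb[1, ] - pad
    dims <- ceiling((bb[2, ] - bb[1, ] + 2 * pad) / voxel)
    if (prod(dims) > 128^3)
        stop("phantom volume would exceed 128^3 voxels; increase voxel size")
    gx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel
    gy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel
    gz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    nn <- .cppClosestVertex(pts, mesh@vertices)
    d <- rowSums((pts - mesh@vertices[nn, , drop = FALSE]) *
                 mesh@normals[nn, , drop = FALSE])
    s <- -d                                  # depth below the surface
    w <- field@cth[nn] * 10
    dens <- ifelse(s < 0, outside,
                   ifelse(s < w, field@cbmd[nn], trabecular))
    vol <- array(dens, dim = dims)
    # separable Gaussian blur
    sg <- imaging$sigma / voxel
    half <- max(1L, ceiling(4 * sg))
    kern <- dnorm(seq(-half, half), 0, sg)
    kern <- kern / sum(kern)
    blur1 <- function(a, dim) {
        idx <- seq_len(dim(a)[dim])
        out <- array(0, dim(a))
        for (o in seq_along(kern)) {
            shift <- o - half - 1L
            src <- pmin(pmax(idx + shift, 1L), dim(a)[dim])
            out <- out + kern[o] * switch(dim,
                a[src, , , drop = FALSE],
                a[, src, , drop = FALSE],
                a[, , src, drop = FALSE])
        }
        out
    }
    vol <- blur1(blur1(blur1(vol, 1L), 2L), 3L)
    list(volume = vol, origin = origin, voxel = voxel)
}

#' Sample intensity profiles from a phantom volume
#'
#' Trilinear interpolation of a rasterised volume along each vertex's
#' outward normal, on the imaging preset's grid.
#'
#' @param phantom result of \code{\link{rasterizePhantomVolume}}.
#' @param mesh the mesh whose vertices/normals define the profile lines.
#' @param imaging imaging preset list.
#' @param vertices integer subset of vertices (default: all).
#' @return An \code{\linkS4class{IntensityProfiles}} object.
#' @export
sampleVolumeProfiles <- function(phantom, mesh, imaging,
                                 vertices = seq_len(nrow(mesh@vertices))) {
    pos <- seq(-imaging$extent, imaging$extent, by = imaging$spacing)
    dims <- dim(phantom$volume)
    interp <- function(p) {
        g <- (p - matrix(phantom$origin, nrow(p), 3,
                         byrow = TRUE)) / phantom$voxel + 0.5
        i0 <- pmin(pmax(floor(g), 1), matrix(dims, nrow(p), 3,
                                             byrow = TRUE) - 1)
        f <- g - i0
        f[f < 0] <- 0; f[f > 1] <- 1
        v <- 0
        for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
            w <- (if (dx) f[, 1] else 1 - f[, 1]) *
                 (if (dy) f[, 2] else 1 - f[, 2]) *
                 (if (dz) f[, 3] else 1 - f[, 3])
            v <- v + w * phantom$volume[cbind(i0[, 1] + dx, i0[, 2] + dy,
                                              i0[, 3] + dz)]
        }
        v
    }
    vals <- matrix(0, length(vertices), length(pos))
    # position increases with depth below the surface (along -normal),
    # matching synthesizeProfiles
    for (k in seq_along(pos)) {
        p <- mesh@vertices[vertices, , drop = FALSE] -
            pos[k] * mesh@normals[vertices, , drop = FALSE]
        vals[, k] <- interp(p)
    }
    new("IntensityProfiles", positions = pos, values = vals,
        imaging = imaging)
}
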