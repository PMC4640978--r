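# Synthetic cohort generation: demographics, planted shape modes, true
# cortical fields and subject meshes.

#' Generate a synthetic cohort table
#'
#' Draws demographics (age, weight, height) from moment-matched truncated
#' normals and planted shape coefficients \code{trueS0 ... trueS(k-1)} from
#' standard normals, with the preset's target correlations between height,
#' weight, age and the size coefficient S0 realised through a joint-Gaussian
#' copula followed by the truncated-normal quantile transform.  Site labels
#' are assigned round-robin after a seeded shuffle, independent of the
#' covariates.
#'
#' @param preset a generator preset, see \code{\link{malePreset}}.
#' @param seed integer seed; the same preset and seed give an identical
#'   table.
#' @return A \code{data.frame} with columns \code{subject_id}, \code{age}
#'   (years), \code{weight} (kg), \code{height} (cm), \code{site} (factor)
#'   and one \code{trueS*} column per planted mode (SD units).
#' @examples
#' coh <- generateCohort(malePreset(n = 40), seed = 1)
#' summary(coh$age)
#' @export
generateCohort <- function(preset, seed) {
    validatePreset(preset)
    n <- preset$n
    k <- length(preset$modeVariances)
    # latent correlation matrix over (age, weight, height, S0)
    R <- diag(4)
    dimnames(R) <- list(c("age", "weight", "height", "S0"),
                        c("age", "weight", "height", "S0"))
    R["height", "S0"] <- R["S0", "height"] <- preset$corr[["height"]]
    R["weight", "S0"] <- R["S0", "weight"] <- preset$corr[["weight"]]
    R["age", "S0"] <- R["S0", "age"] <- preset$corr[["age"]]
    R["height", "weight"] <- R["weight", "height"] <-
        preset$corr[["heightWeight"]]
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch))
        stop("infeasible correlation targets: the implied latent ",
             "correlation matrix is not positive-definite\n",
             paste(capture.output(print(round(R, 3))), collapse = "\n"))
    set.seed(childSeed(seed, 1L))
    Z <- matrix(rnorm(n * 4), n, 4) %*% ch
    colnames(Z) <- colnames(R)
    draw <- function(z, m) {
        p <- tnormSolve(m[["mean"]], m[["sd"]], m[["lo"]], m[["hi"]])
        tnormFromLatent(z, p[["mu"]], p[["sig"]], m[["lo"]], m[["hi"]])
    }
    S <- matrix(rnorm(n * (k - 1L)), n, k - 1L)
    S <- cbind(Z[, "S0"], S)
    colnames(S) <- paste0("trueS", seq_len(k) - 1L)
    site <- rep(preset$sites, length.out = n)[sample.int(n)]
    out <- data.frame(
        subject_id = sprintf("%s%03d", toupper(substr(preset$name, 1, 1)),
                             seq_len(n)),
        age = draw(Z[, "age"], preset$age),
        weight = draw(Z[, "weight"], preset$weight),
        height = draw(Z[, "height"], preset$height),
        site = factor(site, levels = sort(preset$sites)),
        stringsAsFactors = FALSE)
    cbind(out, as.data.frame(S))
}

# smoothstep ramp used to localise mode displacement fields
.smoothstep <- function(x, lo, hi) {
    s <- pmin(1, pmax(0, (x - lo) / (hi - lo)))
    s * s * (3 - 2 * s)
}

#' The generator's planted shape model
#'
#' Constructs the ground-truth shape model used to synthesise subject
#' femurs: mode 0 is anisotropic size (7 percent proximal-distal and
#' 4 percent transverse extent change per SD), mode 1 a neck-shaft-angle
#' rotation of the neck and head about the neck base, mode 2 a femoral
#' neck-axis-length elongation, and the remaining modes smooth low-frequency
#' surface undulations.  The raw displacement fields are orthonormalised by
#' Gram-Schmidt (mode 0 first, so its extent calibration is exact) and
#' scaled so the per-mode variances realise the preset's variance fractions.
#'
#' @param preset a generator preset.
#' @param mesh the canonical mesh (default \code{canonicalFemur()}).
#' @return A \code{\linkS4class{ShapeModel}} whose \code{scores} slot is
#'   empty (it describes the population, not a sample).
#' @export
plantedShapeModel <- function(preset = malePreset(),
                              mesh = canonicalFemur()) {
    key <- paste0("planted-", preset$name, "-",
                  paste(signif(preset$modeVariances, 6), collapse = ","))
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    V <- mesh@vertices
    md <- mesh@metadata
    tpar <- md$ringParameter[md$ring]
    ctr <- colMeans(V)
    n3 <- 3L * nrow(V)
    fields <- list()
    # mode 0: anisotropic size about the centroid.  Registered shapes are
    # re-expressed by rigid Procrustes alignment onto the canonical, so the
    # field is made rigid-free (orthogonal to translations and
    # infinitesimal rotations); for a centred scaling only a tiny rotation
    # component is affected.
    f0 <- cbind(0.04 * (V[, 1] - ctr[1]),
                0.04 * (V[, 2] - ctr[2]),
                0.07 * (V[, 3] - ctr[3]))
    Vc <- sweep(V, 2L, ctr)
    nV <- nrow(V)
    rigidBasis <- qr.Q(qr(cbind(
        c(rep(1, nV), rep(0, 2 * nV)),
        c(rep(0, nV), rep(1, nV), rep(0, nV)),
        c(rep(0, 2 * nV), rep(1, nV)),
        as.vector(cbind(0, -Vc[, 3], Vc[, 2])),
        as.vector(cbind(Vc[, 3], 0, -Vc[, 1])),
        as.vector(cbind(-Vc[, 2], Vc[, 1], 0)))))
    f0v <- as.vector(f0)
    fields[[1]] <- matrix(f0v - rigidBasis %*% crossprod(rigidBasis, f0v),
                          ncol = 3L)
    # mode 1: neck-shaft angle -- linearised rotation of neck+head about the
    # neck base, axis = anterior-posterior
    pivot <- md$centreline[which.min(abs(md$ringParameter - 0.62)), ]
    w <- .smoothstep(tpar, 0.58, 0.74)
    u <- sweep(V, 2L, pivot)
    fields[[2]] <- cbind(w * u[, 3], 0, -w * u[, 1]) * 0.3
    # mode 2: neck axis length
    nd <- md$centreline[which.min(abs(md$ringParameter - 0.92)), ] - pivot
    nd <- nd / sqrt(sum(nd^2))
    fields[[3]] <- outer(w, nd) * 8
    # minor modes: smooth low-frequency surface undulations
    thetaIdx <- rep(seq_len(md$nAround), md$nRings) / md$nAround * 2 * pi
    combos <- list(c(2, 0, 0), c(3, 1, 1), c(1, 2, 2), c(4, 1, 0.5),
                   c(2, 2, 1.5), c(5, 0, 0), c(3, 3, 0.7))
    for (i in seq_along(combos)) {
        cc <- combos[[i]]
        f <- sin(cc[1] * pi * tpar + cc[3]) * cos(cc[2] * thetaIdx + cc[3])
        fields[[3L + i]] <- mesh@normals * f * 2
    }
    # A surface constrains a deformation only up to within-surface flow, so
    # a point-distribution model built from surface registration expresses
    # its modes in the registration's correspondence convention.  The
    # generator adopts the same well-defined convention the registration
    # uses (see nonrigidRegister): a deformation is decomposed into a
    # global affine part plus a normal-directed residual whose scalar
    # field is orthogonal to the normal components of all affine fields.
    # Mode 0 is purely affine; modes 1+ keep only their normal-directed
    # component, with the affine-normal scalar content projected out.
    W <- affineNormalScalars(mesh)
    for (i in 2:length(fields)) {
        s <- rowSums(fields[[i]] * mesh@normals)
        s <- s - W %*% crossprod(W, s)
        fields[[i]] <- mesh@normals * as.vector(s)
    }
    k <- length(preset$modeVariances)
    stopifnot(k <= length(fields))
    M <- vapply(fields[seq_len(k)], function(f) as.vector(f), numeric(n3))
    # Gram-Schmidt, keeping mode 0's direction exactly
    norm0 <- sqrt(sum(M[, 1]^2))
    for (i in seq_len(k)) {
        if (i > 1L) for (j in seq_len(i - 1L))
            M[, i] <- M[, i] - sum(M[, i] * M[, j]) * M[, j]
        M[, i] <- M[, i] / sqrt(sum(M[, i]^2))
    }
    # total variance set so mode 0's calibrated amplitude gives fraction f0
    total <- norm0^2 / preset$modeVariances[1]
    sdev <- sqrt(preset$modeVariances * total)
    new("ShapeModel", mean = as.vector(V), modes = M, sdev = sdev,
        varianceFraction = preset$modeVariances /
            sum(preset$modeVariances),
        scores = matrix(0, 0L, k), template = mesh) -> sm
    .pkgCache[[key]] <- sm
    sm
}

#' Deform the canonical mesh along shape-model modes
#'
#' Applies \code{X = mean + sum_i S_i m_i}: a purely linear construction
#' that leaves the topology unchanged.
#'
#' @param mesh the template mesh (vertex order must match the model).
#' @param S coefficient vector, one entry per leading mode used.
#' @param model a \code{\linkS4class{ShapeModel}}.
#' @param standardized logical; if TRUE (default) \code{S} is in SD units
#'   and is multiplied by the per-mode SD, otherwise \code{S} is in mm.
#' @return A \code{FemurMesh} with deformed vertices.
#' @examples
#' sm <- plantedShapeModel(malePreset())
#' big <- deformMesh(canonicalFemur(), c(1), sm)   # +1 SD of size
#' @export
deformMesh <- function(mesh, S, model, standardized = TRUE) {
    k <- ncol(model@modes)
    if (length(S) > k) stop("more coefficients than modes")
    S <- c(S, rep(0, k - length(S)))
    amp <- if (standardized) S * model@sdev else S
    x <- model@mean + as.vector(model@modes %*% amp)
    V <- vectorToCoords(x)
    new("FemurMesh", vertices = V, faces = mesh@faces,
        normals = vertexNormals(V, mesh@faces), axes = mesh@axes,
        metadata = mesh@metadata)
}

#' The planted superior-neck lesion region
#'
#' The contiguous superior femoral neck / head-neck junction vertex set on
#' the canonical mesh where the generator plants the size-related CMSD
#' deficit.  The frozen default quantification patch
#' (\code{\link{defaultNeckPatch}}) is the morphological core of this
#' region.
#'
#' @param mesh the canonical mesh.
#' @return Integer vertex indices (edge-connected).
#' @export
plantedRegion <- function(mesh = canonicalFemur()) {
    md <- mesh@metadata
    tpar <- md$ringParameter[md$ring]
    off <- mesh@vertices - md$centreline[md$ring, ]
    dirz <- off[, 3] / sqrt(rowSums(off^2))
    which(tpar >= 0.64 & tpar <= 0.86 & dirz > 0.3)
}

#' Generate a subject's true cortical field
#'
#' Builds the noise-free baseline cortical thickness (cm) and density
#' (mg/cm^3) patterns on the canonical vertex set, modulates thickness (by
#' default) inside the planted region multiplicatively by
#' \code{1 + effect/100 * S0}, applies the age slope and site offset, then
#' multiplies by per-vertex log-normal noise.  CMSD is always the product
#' CTh x CBMD.
#'
#' @param subject one row of a cohort table (needs \code{age}, \code{site}
#'   and \code{trueS0}), or a list with those fields.
#' @param preset the generator preset.
#' @param patch integer vertex indices of the planted region (default
#'   \code{plantedRegion()}).
#' @param mesh the canonical mesh.
#' @param seed integer seed for the vertex noise (use \code{NULL} with
#'   \code{noiseSdLog*} = 0 for a deterministic noise-free field).
#' @return A \code{\linkS4class{CorticalMap}} carrying the true fields.
#' @export
generateTrueField <- function(subject, preset, patch = NULL,
                              mesh = canonicalFemur(), seed = NULL) {
    if (is.null(patch)) patch <- plantedRegion(mesh)
    md <- mesh@metadata
    tpar <- md$ringParameter[md$ring]
    theta <- rep(seq_len(md$nAround), md$nRings) / md$nAround * 2 * pi
    cthB <- (1.2 + 1.6 * (1 - tpar)^2 + 0.3 * sin(theta + 1)) / 10  # cm
    cbmdB <- 1050 + 100 * (1 - tpar) + 30 * cos(theta - 0.5)
    fld <- preset$field
    s0 <- subject$trueS0
    if (is.null(s0)) s0 <- 0
    fac <- rep(1, length(cthB))
    fac[patch] <- 1 + preset$patchEffect / 100 * s0
    ageRef <- preset$age[["mean"]]
    ageFac <- 1 + fld$ageSlopePerYear * (subject$age - ageRef)
    siteFac <- 1 + fld$siteOffsets[[as.character(subject$site)]]
    cth <- cthB * ageFac * siteFac
    cbmd <- cbmdB
    eo <- fld$effectOn
    if (identical(eo, "cth")) {
        cth <- cth * fac
    } else if (identical(eo, "cbmd")) {
        cbmd <- cbmd * fac
    } else if (is.numeric(eo)) {      # fraction of the effect on CTh
        cth <- cth * fac^eo
        cbmd <- cbmd * fac^(1 - eo)
    } else stop("unknown effectOn: ", eo)
    if (!is.null(seed)) set.seed(childSeed(seed, 3L))
    if (fld$noiseSdLogCth > 0)
        cth <- cth * rlnorm(length(cth), 0, fld$noiseSdLogCth)
    if (fld$noiseSdLogCbmd > 0)
        cbmd <- cbmd * rlnorm(length(cbmd), 0, fld$noiseSdLogCbmd)
    if (any(cth <= fld$cthFloor)) {
        warning("planted effect drove CTh to or below the floor at ",
                sum(cth <= fld$cthFloor), " vertices; clipped")
        cth <- pmax(cth, fld$cthFloor)
    }
    new("CorticalMap", cth = cth, cbmd = cbmd, cmsd = cth * cbmd,
        flag = rep(FALSE, length(cth)), mesh = mesh)
}

#' Subject meshes for a cohort
#'
#' Deforms the canonical mesh by each subject's planted coefficients and,
#' optionally, applies a small random rigid pose perturbation emulating
#' scanner positioning.
#'
#' @param cohort a cohort table from \code{\link{generateCohort}}.
#' @param model the planted shape model.
#' @param seed integer seed for the pose stream.
#' @param pose logical, apply the preset pose perturbation.
#' @param preset the generator preset (for the pose magnitudes).
#' @return A list of \code{FemurMesh} objects.
#' @export
subjectMeshes <- function(cohort, model, seed, pose = TRUE,
                          preset = malePreset()) {
    mesh <- model@template
    scols <- grep("^trueS", names(cohort))
    set.seed(childSeed(seed, 2L))
    lapply(seq_len(nrow(cohort)), function(i) {
        m <- deformMesh(mesh, as.numeric(cohort[i, scols]), model)
        if (pose) {
            ang <- rnorm(3, 0, preset$pose$rotationSD) * pi / 180
            tr <- rnorm(3, 0, preset$pose$translationSD)
            R <- rotZ(ang[3]) %*% rotY(ang[2]) %*% rotX(ang[1])
            V <- m@vertices %*% t(R)
            V <- sweep(V, 2L, -tr)
            m <- new("FemurMesh", vertices = V, faces = m@faces,
                     normals = m@normals %*% t(R), axes = m@axes,
                     metadata = m@metadata)
        }
        m
    })
}

rotX <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
rotY <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
rotZ <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
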