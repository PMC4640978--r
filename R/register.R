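# Canonical-to-individual surface registration and data transfer.

#' Rigid alignment of the canonical femur to an individual femur
#'
#' Iterative-closest-point minimisation of point-to-point distance over
#' rotation and translation only -- no scaling, since size is signal in
#' this analysis, not nuisance.  Correspondences are symmetric (nearest
#' target vertex for each subsampled source vertex and vice versa), which
#' removes most of the translation bias plain one-directional ICP shows
#' when source and target differ in size; the transform is solved in
#' closed form (Kabsch) each iteration.
#'
#' @param canonical,target \code{FemurMesh} objects in mm; the target pose
#'   is assumed within roughly +/-60 degrees of the canonical pose.
#' @param maxIter maximum ICP iterations.
#' @param tol convergence tolerance on the mean residual change (mm).
#' @param subsample keep every \code{subsample}-th vertex for the
#'   correspondence searches.
#' @return A list with rotation \code{R} (3 x 3), translation \code{t}
#'   (length 3; the map is \code{x \%*\% t(R) + t}) and the final mean
#'   residual (mm).
#' @export
rigidAlign <- function(canonical, target, maxIter = 50L, tol = 1e-4,
                       subsample = 4L) {
    src0 <- canonical@vertices[seq(1L, nrow(canonical@vertices),
                                   by = subsample), , drop = FALSE]
    tv <- target@vertices
    tvs <- tv[seq(1L, nrow(tv), by = subsample), , drop = FALSE]
    R <- diag(3); tr <- colMeans(tv) - colMeans(src0)
    prev <- Inf; worse <- 0L
    for (it in seq_len(maxIter)) {
        src <- sweep(src0 %*% t(R), 2L, tr, "+")
        # forward pairs: source -> nearest target vertex
        idxF <- .cppClosestVertex(src, tv)
        # reverse pairs: target -> nearest source vertex (pre-image in src0)
        srcAll <- sweep(canonical@vertices %*% t(R), 2L, tr, "+")
        idxR <- .cppClosestVertex(tvs, srcAll)
        a <- rbind(src0, canonical@vertices[idxR, , drop = FALSE])
        b <- rbind(tv[idxF, , drop = FALSE], tvs)
        res <- mean(sqrt(rowSums((sweep(a %*% t(R), 2L, tr, "+") - b)^2)))
        if (res > prev * 1.02 + 1e-6) {
            worse <- worse + 1L
            if (worse >= 3L) stop("rigid ICP diverged: residual increased ",
                                  "for 3 consecutive iterations")
        } else worse <- 0L
        if (abs(prev - res) < tol) break
        prev <- res
        ca <- colMeans(a); cb <- colMeans(b)
        H <- crossprod(sweep(a, 2L, ca), sweep(b, 2L, cb))
        sv <- svd(H)
        d <- sign(det(sv$v %*% t(sv$u)))
        R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
        tr <- cb - as.vector(R %*% ca)
    }
    # refinement: linearised point-to-plane iterations remove the
    # vertex-quantisation floor of the coarse phase and the tangential
    # drag that stalls point-to-point matching on near-rotational anatomy
    v2t <- target@metadata$v2t
    if (is.null(v2t)) v2t <- vertexTriangles(target)
    for (it in 1:10) {
        src <- sweep(src0 %*% t(R), 2L, tr, "+")
        cp <- .cppClosestSurfacePoint(src, tv, target@faces, v2t)
        nm <- .matchNormals(target, cp)
        # rows [ (x x n)' n' ] (omega; t) = n . (p - x)
        A <- cbind(src[, 2] * nm[, 3] - src[, 3] * nm[, 2],
                   src[, 3] * nm[, 1] - src[, 1] * nm[, 3],
                   src[, 1] * nm[, 2] - src[, 2] * nm[, 1],
                   nm)
        b <- rowSums(nm * (cp$point - src))
        upd <- tryCatch(qr.solve(A, b), error = function(e) rep(0, 6))
        if (max(abs(upd)) < 1e-10) break
        dR <- rotZ(upd[3]) %*% rotY(upd[2]) %*% rotX(upd[1])
        R <- dR %*% R
        tr <- as.vector(dR %*% tr) + upd[4:6]
    }
    src <- sweep(src0 %*% t(R), 2L, tr, "+")
    cp <- .cppClosestSurfacePoint(src, tv, target@faces, v2t)
    list(R = R, t = tr, residual = mean(cp$distance))
}

applyRigid <- function(V, rigid) sweep(V %*% t(rigid$R), 2L, rigid$t, "+")
invertRigid <- function(V, rigid) sweep(V, 2L, rigid$t) %*% rigid$R

# rigid Procrustes (rotation + translation, no scaling) mapping X onto ref
# with known one-to-one correspondence
procrustesRigid <- function(X, ref) {
    ca <- colMeans(X); cb <- colMeans(ref)
    H <- crossprod(sweep(X, 2L, ca), sweep(ref, 2L, cb))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tr <- cb - as.vector(R %*% ca)
    sweep(X %*% t(R), 2L, tr, "+")
}

# cached (I + lambda L'L) solver for the canonical mesh (uniform graph
# Laplacian); used by the nonrigid displacement solve and reusable across
# subjects
.laplacianSolver <- function(mesh, lambda) {
    key <- sprintf("lap-%d-%g", nrow(mesh@vertices), lambda)
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    n <- nrow(mesh@vertices)
    e <- meshEdges(mesh)
    deg <- tabulate(c(e[, 1], e[, 2]), n)
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
    L <- Matrix::Diagonal(x = rep(1, n)) -
        Matrix::Diagonal(x = 1 / deg) %*% W
    LtL <- Matrix::crossprod(L)
    A <- Matrix::Diagonal(n) + lambda * LtL
    sol <- list(chol = Matrix::Cholesky(A, LDL = FALSE), LtL = LtL)
    .pkgCache[[key]] <- sol
    sol
}

# candidate triangle lists within a 3-ring, for the normal-shooting search
.deepCandidates <- function(mesh) {
    n <- nrow(mesh@vertices)
    f <- mesh@faces
    key <- sprintf("cand3-%d-%d-%.0f", n, nrow(f), sum(as.numeric(f)))
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    adj <- meshAdjacency(mesh)
    v2t <- vertexTriangles(mesh)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        r1 <- adj[[i]]
        r2 <- unique(unlist(adj[r1]))
        r3 <- unique(unlist(adj[r2]))
        out[[i]] <- unique(unlist(v2t[unique(c(i, r1, r2, r3))]))
    }
    .pkgCache[[key]] <- out
    out
}

# interpolated outward target normals at matched surface points
.matchNormals <- function(target, cp) {
    tri <- target@faces[cp$triangle, , drop = FALSE]
    N <- cp$bary[, 1] * target@normals[tri[, 1], , drop = FALSE] +
         cp$bary[, 2] * target@normals[tri[, 2], , drop = FALSE] +
         cp$bary[, 3] * target@normals[tri[, 3], , drop = FALSE]
    N / sqrt(rowSums(N^2))
}

#' Nonrigid registration of the canonical femur to an individual femur
#'
#' After rigid alignment, each vertex is matched by normal shooting --
#' intersecting the ray along its canonical normal with the target
#' surface -- and the cumulative displacement scalars are decomposed into
#' a global affine part (trimmed least squares against the normal
#' components of the 12 affine basis fields) plus a Laplacian-smoothed
#' normal-directed residual, iterating with a decreasing regularisation
#' schedule.  Missed or wrong-sheet (grazing) rays carry no weight; the
#' smoothness prior fills them in.
#' A surface constrains a deformation only up to within-surface sliding,
#' so some convention must pick the tangential motion.  The convention
#' here -- deformation = affine part + normal-directed residual whose
#' scalar field is orthogonal to the normal components of affine fields --
#' is reproducible and is the convention in which point-distribution
#' models built from regularised surface registration are expressed.
#'
#' The returned coordinates are re-expressed in the canonical frame by a
#' final correspondence-based rigid Procrustes alignment onto the
#' canonical vertices (rotation and translation only -- never scale), so
#' scanner pose does not leak into downstream shape statistics while the
#' target's size is fully preserved.
#'
#' @param canonical,target \code{FemurMesh} objects.
#' @param lambdaSchedule decreasing Laplacian regularisation weights; one
#'   match/decompose/solve iteration is run per entry.
#' @param tolerance mean point-to-surface residual (mm) above which the
#'   subject is flagged with a warning.
#' @param rigid optional precomputed rigid transform.
#' @param rayMax maximum normal-shooting ray length (mm).
#' @param v2t optional precomputed \code{vertexTriangles(target)} (subject
#'   meshes sharing one topology can share it).
#' @return A \code{\linkS4class{Correspondence}}; its \code{deformed} slot
#'   holds the deformed canonical coordinates (5580 x 3 = 16740 values),
#'   Procrustes-aligned to the canonical frame.
#' @export
nonrigidRegister <- function(canonical, target,
                             lambdaSchedule = c(5, 2, 1, 0.5, 0.2, 0.1,
                                                0.05),
                             tolerance = 0.5, rigid = NULL, rayMax = 12,
                             v2t = NULL) {
    if (is.null(rigid)) rigid <- rigidAlign(canonical, target)
    X0 <- applyRigid(canonical@vertices, rigid)
    n0 <- canonical@normals %*% t(rigid$R)
    if (is.null(v2t)) v2t <- target@metadata$v2t
    if (is.null(v2t)) v2t <- vertexTriangles(target)
    cand <- .deepCandidates(canonical)   # same topology as the canonical
    nC <- nrow(X0); nT <- nrow(target@vertices)
    # affine basis fields on the aligned canonical
    h <- cbind(X0, 1)
    Z <- vector("list", 12L)
    k <- 0L
    for (cc in 1:3) for (j in 1:4) {
        k <- k + 1L
        Z[[k]] <- matrix(0, nC, 3L)
        Z[[k]][, cc] <- h[, j]
    }

    X <- X0

    # normal-shooting scalar iteration ------------------------------------
    raw <- vapply(Z, function(F) rowSums(n0 * F), numeric(nC))
    # Tikhonov term on the *tangential* magnitude of the affine field:
    # affine directions that are everywhere near-tangential (e.g. rotation
    # about the axis of a surface of revolution) have almost no normal
    # component, so the scalar data cannot pin them, yet they would move
    # vertices tangentially by millimetres; identifiable directions are
    # biased only at the 1e-4 level.
    Gz <- matrix(0, 12, 12)
    for (a in 1:12) for (b in a:12) {
        Gz[a, b] <- sum(Z[[a]] * Z[[b]]); Gz[b, a] <- Gz[a, b]
    }
    Gr <- crossprod(raw)
    ridge <- 1e-4 * (Gz - Gr) + 1e-10 * mean(diag(Gr)) * diag(12)
    LtL <- .laplacianSolver(canonical, 1)$LtL
    for (lambda in lambdaSchedule) {
        # rays along the *canonical* normals (rigid-rotated): in the
        # affine-plus-normal-displacement convention the line
        # {X0 + Z alpha + t n0} contains the true correspondent at any
        # amplitude, so matching stays consistent for extreme shapes
        rs <- .cppRayShoot(X, n0, target@vertices, target@faces, cand,
                           rayMax)
        # hit selection: nearest |t| -- but where a second sheet lies
        # within 3 mm of the first (e.g. head and neck surfaces both in
        # range), the match is ambiguous and carries no weight during the
        # coarse iterations; the smoothness prior fills such regions in
        # until the estimate has moved close enough to disambiguate
        ok <- rs$nhit >= 1L
        if (lambda >= 0.5)
            ok <- ok & !(rs$nhit >= 2L &
                         abs(rs$t[, 2]) - abs(rs$t[, 1]) < 3)
        okw <- which(ok)
        tri <- target@faces[rs$triangle[okw, 1], , drop = FALSE]
        bw <- rs$bary[okw, 1:3, drop = FALSE]
        # each hit is measured at its *own* canonical pre-image (same
        # topology): barycentric combination of the aligned canonical
        # vertices and normals of the hit triangle.  Anchoring the
        # measurement to the hit parameter, rather than the ray origin,
        # removes the feedback bias that would otherwise couple affine
        # misestimates to the bump gradients at large amplitudes.
        q0 <- bw[, 1] * X0[tri[, 1], ] + bw[, 2] * X0[tri[, 2], ] +
              bw[, 3] * X0[tri[, 3], ]
        n0q <- bw[, 1] * n0[tri[, 1], ] + bw[, 2] * n0[tri[, 2], ] +
               bw[, 3] * n0[tri[, 3], ]
        n0q <- n0q / sqrt(rowSums(n0q^2))
        hit <- X[okw, , drop = FALSE] + rs$t[okw, 1] * n0[okw, ,
                                                          drop = FALSE]
        # gate: drop hits whose target surface normal is nearly
        # perpendicular to the pre-image normal (wrong-sheet matches)
        hn <- .matchNormals(target, list(triangle = rs$triangle[okw, 1],
                                         bary = bw))
        keep <- abs(rowSums(hn * n0q)) > 0.3
        okw <- okw[keep]
        q0 <- q0[keep, , drop = FALSE]
        n0q <- n0q[keep, , drop = FALSE]
        hit <- hit[keep, , drop = FALSE]
        tri <- tri[keep, , drop = FALSE]
        bw <- bw[keep, , drop = FALSE]
        U <- hit - q0
        uq <- rowSums(n0q * U)
        qh <- cbind(q0, 1)
        rawq <- cbind(n0q[, 1] * qh, n0q[, 2] * qh, n0q[, 3] * qh)
        # joint fit of the affine scalars and the smooth residual,
        #   min |rawq a + B d - u|^2 + lambda |L d|^2  (+ small ridge on a)
        # via the Schur complement over the 12 affine coefficients.
        # Fitting them jointly matters: samples lost to gating or
        # ambiguity are spatially structured, and a sequential affine
        # fit would absorb the unexplained bump content into the affine
        # part, biasing the size estimate at large amplitudes.
        B <- Matrix::sparseMatrix(i = rep(seq_along(okw), 3L),
                                  j = as.integer(tri),
                                  x = as.numeric(bw),
                                  dims = c(length(okw), nC))
        BtB <- Matrix::crossprod(B)
        BtR <- as.matrix(Matrix::crossprod(B, rawq))     # nC x 12
        Btu <- as.vector(Matrix::crossprod(B, uq))
        # The generator-shared convention defines the affine part by a
        # plain (unweighted, full-vertex) projection of the displacement
        # scalars onto the affine-normal basis; the planted residual
        # scalars are orthogonal to that basis in exactly this metric.
        # Samples lost to gating/ambiguity are spatially structured, so
        # fitting on the raw samples would leak residual content into
        # the size estimate.  Completing the field over all vertices
        # first (lightly smoothed scatter with smoothness fill in the
        # gaps) restores the metric before the projection.
        K <- Matrix::Cholesky(Matrix::forceSymmetric(
            BtB + lambda * LtL), LDL = FALSE)
        if (lambda >= 0.5) {
            # coarse iterations: sampled least squares is accurate enough
            # while the estimate is still moving
            ab <- solve(crossprod(rawq) + ridge, crossprod(rawq, uq))
        } else {
            uFull <- as.vector(Matrix::solve(K, Btu))
            ab <- solve(Gr + ridge, crossprod(raw, uFull))
        }
        # residual at the schedule smoothness, with the affine fixed
        d <- as.vector(Matrix::solve(K, Btu - BtR %*% ab))
        ZA <- matrix(0, nC, 3L)
        for (j in 1:12) ZA <- ZA + Z[[j]] * ab[j]
        X <- X0 + ZA + n0 * d
    }
    cp <- .cppClosestSurfacePoint(X, target@vertices, target@faces, v2t)
    res <- cp$distance
    if (mean(res) > tolerance)
        warning(sprintf("nonrigid registration residual %.3f mm exceeds %g mm; subject flagged",
                        mean(res), tolerance))
    bary <- cp$bary
    bary[bary < 0] <- 0
    bary <- bary / rowSums(bary)
    deformed <- procrustesRigid(X, canonical@vertices)
    # quality control: RMS Laplacian of the recovered displacement field.
    # Wrong-sheet matches leave kinks in the field, so high roughness
    # marks registrations that converged to a mis-correspondence even
    # when the surfaces coincide (sliding is invisible to the residual).
    rough <- sqrt(mean(as.matrix(
        LtL %*% (deformed - canonical@vertices))^2))
    if (rough > 0.2)
        warning(sprintf("displacement roughness %.2f mm is high; registration flagged",
                        rough))
    new("Correspondence", deformed = deformed,
        triangle = as.integer(cp$triangle), bary = bary,
        residual = res, roughness = rough, rigid = rigid)
}

#' Transfer a per-vertex field from the individual to the canonical mesh
#'
#' Barycentric interpolation of the individual's per-vertex values at each
#' canonical vertex's matched surface point.  Missing (flagged) source
#' vertices are excluded and their weight renormalised; a canonical vertex
#' whose three source corners are all missing becomes \code{NA}.
#'
#' @param values numeric per-vertex values on the individual mesh (or a
#'   \code{CorticalMap}, in which case all three fields are transferred).
#' @param correspondence a \code{\linkS4class{Correspondence}}.
#' @param targetFaces the individual mesh's face matrix.
#' @param missingLimit fraction of missing canonical values above which the
#'   subject is flagged with a warning.
#' @return Numeric vector over canonical vertices (or a 3-column matrix for
#'   a \code{CorticalMap} input), with attribute \code{"missing"}.
#' @export
transferData <- function(values, correspondence, targetFaces,
                         missingLimit = 0.2) {
    if (is(values, "CorticalMap")) {
        v <- values
        out <- cbind(
            cth = transferData(ifelse(v@flag, NA, v@cth), correspondence,
                               targetFaces, missingLimit),
            cbmd = transferData(ifelse(v@flag, NA, v@cbmd), correspondence,
                                targetFaces, missingLimit),
            cmsd = transferData(ifelse(v@flag, NA, v@cmsd), correspondence,
                                targetFaces, missingLimit))
        return(out)
    }
    tri <- targetFaces[correspondence@triangle, , drop = FALSE]
    vals <- matrix(values[tri], ncol = 3L)
    w <- correspondence@bary
    w[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    den <- rowSums(w)
    out <- ifelse(den > 0, rowSums(w * vals) / den, NA_real_)
    miss <- mean(is.na(out))
    if (miss > missingLimit)
        warning(sprintf("%.1f%% of transferred values missing; subject flagged",
                        100 * miss))
    attr(out, "missing") <- miss
    out
}

#' Smooth a per-vertex field on a mesh
#'
#' Iterated neighbour averaging whose accumulated kernel approximates a
#' Gaussian of the requested full-width-half-maximum on the mesh: each
#' iteration replaces a vertex value by \code{(1-alpha)} times itself plus
#' \code{alpha} times its 1-ring mean, adding about
#' \code{alpha * h^2 / 2} of kernel variance per axis per iteration for mean
#' edge length \code{h}; the iteration count is chosen accordingly.
#' Missing values are excluded from the averages (weights renormalised) and
#' stay missing.
#'
#' @param values numeric vector over vertices, or a vertices x k matrix
#'   (columns smoothed together).
#' @param mesh the mesh.
#' @param fwhm target full-width-half-maximum in mm; 0 is the identity.
#' @param alpha per-iteration blending weight in (0, 1].
#' @return Smoothed values, same shape as the input.
#' @export
smoothSurface <- function(values, mesh, fwhm = 10, alpha = 0.5) {
    stopifnot(fwhm >= 0)
    if (fwhm == 0) return(values)
    h <- meanEdgeLength(mesh)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    k <- max(1L, as.integer(round(2 * sigma^2 / (alpha * h^2))))
    vec <- is.null(dim(values))
    X <- if (vec) matrix(values, ncol = 1L) else as.matrix(values)
    n <- nrow(mesh@vertices)
    key <- sprintf("adjmat-%d", n)
    A <- .pkgCache[[key]]
    if (is.null(A)) {
        e <- meshEdges(mesh)
        A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]),
                                  j = c(e[, 2], e[, 1]), x = 1,
                                  dims = c(n, n))
        .pkgCache[[key]] <- A
    }
    ok <- !is.na(X)
    X0 <- X; X0[!ok] <- 0
    okn <- as.matrix(A %*% ok)      # available-neighbour counts
    for (it in seq_len(k)) {
        nb <- as.matrix(A %*% X0)
        mean_nb <- ifelse(okn > 0, nb / okn, X0)
        X0 <- (1 - alpha) * X0 + alpha * mean_nb
        X0[!ok] <- 0
    }
    X0[!ok] <- NA
    if (vec) as.vector(X0) else X0
}

#' Register a whole cohort to the canonical femur
#'
#' Convenience wrapper: runs \code{\link{nonrigidRegister}} for each subject
#' mesh and collects the deformed coordinate vectors into an
#' n x 16740 matrix plus the list of correspondences.
#'
#' @param canonical the canonical mesh.
#' @param meshes list of subject \code{FemurMesh} objects.
#' @param ... passed to \code{\link{nonrigidRegister}}.
#' @param verbose print progress every 25 subjects.
#' @return List with \code{X} (subjects x 16740) and
#'   \code{correspondences}.
#' @export
registerCohort <- function(canonical, meshes, ..., verbose = FALSE) {
    n <- length(meshes)
    X <- matrix(0, n, 3L * nrow(canonical@vertices))
    corrs <- vector("list", n)
    # subject meshes usually share one topology: compute the incident-
    # triangle table once when they all match the first mesh
    shared <- all(vapply(meshes, function(m)
        identical(dim(m@faces), dim(meshes[[1]]@faces)) &&
            all(m@faces == meshes[[1]]@faces), logical(1)))
    v2t <- if (shared) vertexTriangles(meshes[[1]]) else NULL
    for (i in seq_len(n)) {
        corrs[[i]] <- nonrigidRegister(canonical, meshes[[i]], v2t = v2t,
                                       ...)
        X[i, ] <- coordsToVector(corrs[[i]]@deformed)
        if (verbose && i %% 25L == 0L)
            message("registered ", i, "/", n)
    }
    list(X = X, correspondences = corrs,
         residual = vapply(corrs, function(cc) mean(cc@residual), 0),
         roughness = vapply(corrs, function(cc) cc@roughness, 0))
}
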