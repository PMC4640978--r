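# Mesh construction and utilities.

.pkgCache <- new.env(parent = emptyenv())

#' Construct a FemurMesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of outward unit normals; computed
#'   from the triangulation when omitted.
#' @param axes named list of unit 3-vectors labelling anatomical directions.
#' @param metadata free-form annotation list.
#' @return A \code{\linkS4class{FemurMesh}}.
#' @export
FemurMesh <- function(vertices, faces, normals = NULL, axes = list(),
                      metadata = list()) {
    vertices <- as.matrix(vertices)
    storage.mode(vertices) <- "double"
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (is.null(normals))
        normals <- vertexNormals(vertices, faces)
    new("FemurMesh", vertices = vertices, faces = faces,
        normals = as.matrix(normals), axes = axes, metadata = metadata)
}

#' Area-weighted outward vertex normals
#'
#' Face normals are accumulated per vertex weighted by face area; the result
#' is normalised.  Orientation follows the face winding; use
#' \code{orientOutward} to force outward orientation against a reference
#' interior point set.
#'
#' @param vertices n x 3 matrix.
#' @param faces m x 3 matrix.
#' @return n x 3 matrix of unit normals.
#' @export
vertexNormals <- function(vertices, faces) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c_ <- vertices[faces[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c_ - a
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    n <- matrix(0, nrow(vertices), 3L)
    for (k in 1:3) {
        n[, 1] <- n[, 1] + tapply2(fn[, 1], faces[, k], nrow(vertices))
        n[, 2] <- n[, 2] + tapply2(fn[, 2], faces[, k], nrow(vertices))
        n[, 3] <- n[, 3] + tapply2(fn[, 3], faces[, k], nrow(vertices))
    }
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n / len
}

# rowsum-based accumulation returning a full-length vector
tapply2 <- function(x, idx, n) {
    out <- numeric(n)
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
    out
}

# Rotation-minimising frames along a polyline (double-reflection method).
.rmFrames <- function(points) {
    n <- nrow(points)
    tangents <- rbind(points[2, ] - points[1, ],
                      (points[3:n, ] - points[1:(n - 2), ]) / 2,
                      points[n, ] - points[n - 1, ])
    tangents <- tangents / sqrt(rowSums(tangents^2))
    r <- matrix(0, n, 3L)
    up <- c(1, 0, 0)
    r0 <- up - sum(up * tangents[1, ]) * tangents[1, ]
    r[1, ] <- r0 / sqrt(sum(r0^2))
    for (i in seq_len(n - 1)) {
        v1 <- points[i + 1, ] - points[i, ]
        c1 <- sum(v1 * v1)
        rL <- r[i, ] - (2 / c1) * sum(v1 * r[i, ]) * v1
        tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
        v2 <- tangents[i + 1, ] - tL
        c2 <- sum(v2 * v2)
        ri <- if (c2 > 1e-12) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
        ri <- ri - sum(ri * tangents[i + 1, ]) * tangents[i + 1, ]
        r[i + 1, ] <- ri / sqrt(sum(ri^2))
    }
    s <- cbind(tangents[, 2] * r[, 3] - tangents[, 3] * r[, 2],
               tangents[, 3] * r[, 1] - tangents[, 1] * r[, 3],
               tangents[, 1] * r[, 2] - tangents[, 2] * r[, 1])
    list(tangent = tangents, n1 = r, n2 = s)
}

#' The synthetic canonical proximal femur
#'
#' A smooth, blended proximal-femur surface (femoral head sphere, neck
#' frustum, trochanteric bulge and shaft cylinder) swept as a generalised
#' cylinder over a curved centreline: 93 rings of 60 vertices = 5580
#' vertices.  It is a synthetic stand-in for a population-averaged canonical
#' surface: self-contained, deterministic, with labelled anatomical axes
#' (\code{proximalDistal} = +z, \code{medialLateral} = +x,
#' \code{anteriorPosterior} = +y) and a regular quad-grid triangulation.
#' The result is cached within the session.
#'
#' @return A \code{\linkS4class{FemurMesh}} with 5580 vertices.
#' @examples
#' mesh <- canonicalFemur()
#' nrow(vertices(mesh))
#' @export
canonicalFemur <- function() {
    if (!is.null(.pkgCache$canonical)) return(.pkgCache$canonical)
    nRings <- 93L; nAround <- 60L
    tk <- c(0, 0.2, 0.35, 0.5, 0.62, 0.72, 0.82, 0.92, 1)
    cx <- splinefun(tk, c(0, 0, 0, 0, 6, 16, 27, 37, 44), method = "natural")
    cy <- splinefun(tk, c(0, 0, 0, 0.5, 1.5, 2.5, 3, 3, 3),
                    method = "natural")
    cz <- splinefun(tk, c(-100, -70, -45, -18, -4, 7, 16, 23, 28),
                    method = "natural")
    rk <- c(0, 0.2, 0.35, 0.5, 0.58, 0.66, 0.74, 0.82, 0.9, 1)
    rb <- splinefun(rk, c(13.5, 13.8, 14.5, 16.5, 18.5, 16.5, 15.5,
                          17.5, 21.5, 13), method = "natural")
    tt <- seq(0, 1, length.out = nRings)
    centre <- cbind(cx(tt), cy(tt), cz(tt))
    fr <- .rmFrames(centre)
    theta <- seq(0, 2 * pi, length.out = nAround + 1L)[seq_len(nAround)]
    trochW <- exp(-0.5 * ((tt - 0.56) / 0.06)^2)   # greater trochanter
    V <- matrix(0, nRings * nAround, 3L)
    ringIdx <- rep(seq_len(nRings), each = nAround)
    for (i in seq_len(nRings)) {
        dir <- outer(cos(theta), fr$n1[i, ]) + outer(sin(theta), fr$n2[i, ])
        lateral <- pmax(0, -dir[, 1])              # bulge on the lateral side
        r <- rb(tt[i]) + 6 * trochW[i] * lateral
        rows <- (i - 1L) * nAround + seq_len(nAround)
        V[rows, ] <- centre[rep(i, nAround), ] + dir * r
    }
    F1 <- matrix(0L, 2L * (nRings - 1L) * nAround, 3L)
    k <- 1L
    for (i in seq_len(nRings - 1L)) {
        for (j in seq_len(nAround)) {
            jn <- if (j == nAround) 1L else j + 1L
            a <- (i - 1L) * nAround + j
            b <- (i - 1L) * nAround + jn
            c_ <- i * nAround + j
            d <- i * nAround + jn
            F1[k, ] <- c(a, b, d); F1[k + 1L, ] <- c(a, d, c_)
            k <- k + 2L
        }
    }
    nrm <- vertexNormals(V, F1)
    # orient outward: against the offset direction from the local centre
    off <- V - centre[ringIdx, ]
    flip <- rowSums(nrm * off) < 0
    nrm[flip, ] <- -nrm[flip, ]
    mesh <- new("FemurMesh", vertices = V, faces = F1, normals = nrm,
                axes = list(proximalDistal = c(0, 0, 1),
                            medialLateral = c(1, 0, 0),
                            anteriorPosterior = c(0, 1, 0)),
                metadata = list(name = "canonical-synthetic",
                                nRings = nRings, nAround = nAround,
                                ringParameter = tt, ring = ringIdx,
                                centreline = centre))
    .pkgCache$canonical <- mesh
    mesh
}

#' Mesh adjacency structures
#'
#' \code{meshEdges} returns the unique undirected edge list;
#' \code{meshAdjacency} the per-vertex neighbour list; \code{meshGraph} an
#' igraph graph (used for cluster connectivity).
#'
#' @param mesh a \code{FemurMesh}.
#' @return See description.
#' @export
meshEdges <- function(mesh) {
    f <- mesh@faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    unique(e)
}

#' @rdname meshEdges
#' @export
meshAdjacency <- function(mesh) {
    key <- "adjacency"
    cached <- attr(mesh, key, exact = TRUE)
    e <- meshEdges(mesh)
    n <- nrow(mesh@vertices)
    adj <- vector("list", n)
    both <- rbind(e, e[, 2:1])
    sp <- split(both[, 2], both[, 1])
    adj[as.integer(names(sp))] <- lapply(sp, as.integer)
    adj
}

#' @rdname meshEdges
#' @export
meshGraph <- function(mesh) {
    igraph::graph_from_edgelist(meshEdges(mesh), directed = FALSE)
}

#' Mean edge length of a mesh (mm)
#' @param mesh a \code{FemurMesh}.
#' @export
meanEdgeLength <- function(mesh) {
    e <- meshEdges(mesh)
    d <- mesh@vertices[e[, 1], ] - mesh@vertices[e[, 2], ]
    mean(sqrt(rowSums(d^2)))
}

#' Per-vertex (barycentric) surface areas, mm^2
#' @param mesh a \code{FemurMesh}.
#' @export
vertexAreas <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    e1 <- v[f[, 2], ] - v[f[, 1], ]
    e2 <- v[f[, 3], ] - v[f[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    fa <- 0.5 * sqrt(rowSums(cr^2))
    out <- numeric(nrow(v))
    for (k in 1:3)
        out <- out + tapply2(fa / 3, f[, k], nrow(v))
    out
}

#' Morphological operations on vertex patches
#'
#' \code{erodePatch} removes, \code{dilatePatch} adds, one 1-ring of
#' boundary vertices per iteration.
#'
#' @param indices integer vertex indices.
#' @param mesh the mesh defining adjacency.
#' @param iterations number of 1-ring steps.
#' @return integer vertex indices.
#' @export
erodePatch <- function(indices, mesh, iterations = 1L) {
    adj <- meshAdjacency(mesh)
    inset <- logical(nrow(mesh@vertices))
    inset[indices] <- TRUE
    for (it in seq_len(iterations)) {
        keep <- vapply(which(inset), function(i) all(inset[adj[[i]]]),
                       logical(1))
        inset[which(inset)[!keep]] <- FALSE
    }
    which(inset)
}

#' @rdname erodePatch
#' @export
dilatePatch <- function(indices, mesh, iterations = 1L) {
    adj <- meshAdjacency(mesh)
    inset <- logical(nrow(mesh@vertices))
    inset[indices] <- TRUE
    for (it in seq_len(iterations)) {
        add <- unique(unlist(adj[which(inset)]))
        inset[add] <- TRUE
    }
    which(inset)
}

#' Bounding extent of a shape along a labelled anatomical axis
#'
#' @param x a \code{FemurMesh}, an n x 3 coordinate matrix or a 3n
#'   concatenated coordinate vector.
#' @param axis a unit 3-vector or the name of an axis of the canonical mesh.
#' @param mesh mesh supplying named axes when \code{axis} is a name.
#' @return Extent (max minus min projection) in mm.
#' @export
boundingExtent <- function(x, axis, mesh = NULL) {
    if (is(x, "FemurMesh")) { mesh <- x; x <- x@vertices }
    if (is.character(axis)) {
        if (is.null(mesh) || is.null(mesh@axes[[axis]]))
            stop("axis '", axis, "' is not labelled on this mesh")
        axis <- mesh@axes[[axis]]
    }
    if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = FALSE,
                                     dimnames = NULL)
    p <- as.vector(x %*% axis)
    diff(range(p))
}

# concatenated 3n vector <-> n x 3 matrix (x1..xn, y1..yn, z1..zn layout)
coordsToVector <- function(v) as.vector(v)
vectorToCoords <- function(x) matrix(x, ncol = 3L)

# Orthonormal basis (columns) of the normal components of the 12 affine
# vector fields on a mesh: scalars n_c(v) * h_j(v) for coordinate c and
# homogeneous coordinate h in (x, y, z, 1).  Used to decompose a surface
# deformation into its affine part and a normal-directed residual in a
# reproducible way (see nonrigidRegister).
affineNormalScalars <- function(mesh, vertices = mesh@vertices,
                                normals = mesh@normals) {
    h <- cbind(vertices, 1)
    cols <- vector("list", 12L)
    k <- 0L
    for (cc in 1:3) for (j in 1:4) {
        k <- k + 1L
        cols[[k]] <- normals[, cc] * h[, j]
    }
    qr.Q(qr(do.call(cbind, cols)))
}

# incident triangles per vertex, extended over the 1-ring (for the
# closest-surface-point search)
vertexTriangles <- function(mesh) {
    f <- mesh@faces
    n <- nrow(mesh@vertices)
    key <- sprintf("v2t-%d-%d-%.0f", n, nrow(f), sum(as.numeric(f)))
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    v2t <- vector("list", n)
    idx <- rep(seq_len(nrow(f)), 3L)
    vv <- as.integer(f)
    sp <- split(idx, vv)
    v2t[as.integer(names(sp))] <- sp
    adj <- meshAdjacency(mesh)
    out <- lapply(seq_len(n), function(i)
        as.integer(unique(unlist(v2t[c(i, adj[[i]])]))))
    .pkgCache[[key]] <- out
    out
}
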