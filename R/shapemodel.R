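# Point-based statistical shape model by PCA of registered coordinates.

#' Build a statistical shape model
#'
#' Principal component analysis of the n registered coordinate vectors
#' X_j (16740 elements each for the canonical femur): the mean shape is
#' the arithmetic mean, and the modes are the leading eigenvectors of the
#' sample covariance, computed through the n x n Gram matrix (the
#' 16740 x 16740 covariance is never formed).  Modes are sorted by
#' descending eigenvalue, and each mode's sign is fixed so its
#' largest-magnitude component is positive, making coefficients
#' reproducible.  No size normalisation is applied before the PCA --
#' deliberately, so that size remains in the leading mode.
#'
#' @param X numeric matrix, subjects x coordinates (n x 16740), each row a
#'   registered shape.
#' @param template the canonical \code{FemurMesh} (topology and axes).
#' @param tol eigenvalues below \code{tol * max(eigenvalue)} are dropped.
#' @return A \code{\linkS4class{ShapeModel}} with per-subject scores.
#' @examples
#' sm <- plantedShapeModel(malePreset())
#' S <- matrix(rnorm(40), 20, 2)
#' X <- t(apply(S, 1, function(s)
#'     shapeMean(sm) + shapeModes(sm)[, 1:2] %*% (s * modeSD(sm)[1:2])))
#' fit <- buildShapeModel(X)
#' round(varianceFraction(fit), 3)
#' @export
buildShapeModel <- function(X, template = canonicalFemur(), tol = 1e-10) {
    n <- nrow(X)
    stopifnot(n >= 3L)
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    G <- tcrossprod(Xc) / (n - 1)
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values
    keep <- which(lam > tol * max(lam, 0) & lam > 0)
    keep <- head(keep, n - 1L)
    if (length(keep) < length(lam) - 1L && n > 3L)
        message("shape model rank ", length(keep), " < n - 1 = ", n - 1L,
                " (duplicate or dependent shapes)")
    lam <- lam[keep]
    U <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])
    U <- sweep(U, 2L, sqrt((n - 1) * lam), "/")
    # sign convention: largest-magnitude component positive
    for (j in seq_len(ncol(U))) {
        i <- which.max(abs(U[, j]))
        if (U[i, j] < 0) U[, j] <- -U[, j]
    }
    scores <- Xc %*% U
    new("ShapeModel", mean = mu, modes = U, sdev = sqrt(lam),
        varianceFraction = lam / sum(lam), scores = scores,
        template = template)
}

#' Project a shape onto the model's modes
#'
#' Computes the coefficients \code{S_i = (X - mean) . m_i}; the
#' standardised variant divides by each mode's SD so coefficients are in
#' SD units.
#'
#' @param x a 16740-vector, an n x 3 coordinate matrix, or a
#'   \code{FemurMesh}.
#' @param model a \code{\linkS4class{ShapeModel}}.
#' @param standardized logical.
#' @return Numeric coefficient vector, one entry per mode.
#' @export
projectShape <- function(x, model, standardized = FALSE) {
    if (is(x, "FemurMesh")) x <- x@vertices
    if (!is.null(dim(x))) x <- coordsToVector(as.matrix(x))
    s <- as.vector(crossprod(model@modes, x - model@mean))
    if (standardized) s <- s / ifelse(model@sdev > 0, model@sdev, 1)
    s
}

#' Reconstruct a shape from model coefficients
#'
#' @param S coefficient vector (raw mm units unless
#'   \code{standardized}).
#' @param model a \code{ShapeModel}.
#' @param standardized logical; multiply by mode SDs first.
#' @return A 16740-element coordinate vector.
#' @export
reconstructShape <- function(S, model, standardized = FALSE) {
    k <- ncol(model@modes)
    S <- c(S, rep(0, k - length(S)))
    if (standardized) S <- S * model@sdev
    model@mean + as.vector(model@modes %*% S)
}

#' Percent extent change per SD of a shape mode
#'
#' Compares the bounding extents of the mean shape deformed by plus and
#' minus one mode SD along a labelled anatomical axis:
#' \code{100 * (extent(+1SD) - extent(-1SD)) / (2 * extent(mean))}.
#'
#' @param model a \code{ShapeModel}.
#' @param mode 1-based mode index (mode 1 = largest eigenvalue).
#' @param axis axis name on the template mesh (e.g.
#'   \code{"proximalDistal"}) or a unit 3-vector.
#' @return Signed percent change per SD.
#' @export
modeExtentChange <- function(model, mode, axis) {
    tmpl <- model@template
    if (is.character(axis) && is.null(tmpl@axes[[axis]]))
        stop("axis '", axis, "' is not labelled on the template mesh")
    if (model@sdev[mode] == 0) return(0)
    plus <- reconstructShape(ifelse(seq_len(ncol(model@modes)) == mode,
                                    model@sdev[mode], 0), model)
    minus <- reconstructShape(ifelse(seq_len(ncol(model@modes)) == mode,
                                     -model@sdev[mode], 0), model)
    e0 <- boundingExtent(vectorToCoords(model@mean), axis, tmpl)
    ep <- boundingExtent(vectorToCoords(plus), axis, tmpl)
    em <- boundingExtent(vectorToCoords(minus), axis, tmpl)
    100 * (ep - em) / (2 * e0)
}

#' Orient a mode so +1 SD increases extent along an axis
#'
#' PCA mode signs are arbitrary (fixed here only by the
#' largest-component-positive convention), but interpretation -- "larger
#' femur" -- needs a reproducible direction.  This flips the mode (and its
#' scores) if one positive SD currently shrinks the extent along the given
#' axis.
#'
#' @param model a \code{ShapeModel}.
#' @param mode 1-based mode index.
#' @param axis axis name or unit vector (default proximal-distal).
#' @return The (possibly flipped) model.
#' @export
orientMode <- function(model, mode = 1L, axis = "proximalDistal") {
    if (modeExtentChange(model, mode, axis) < 0) {
        model@modes[, mode] <- -model@modes[, mode]
        if (nrow(model@scores))
            model@scores[, mode] <- -model@scores[, mode]
    }
    model
}

#' Export mode-extreme meshes for visualisation
#'
#' Writes (or returns) the mean shape deformed by plus and minus k mode
#' SDs, the standard way of displaying what a shape mode does.
#'
#' @param model a \code{ShapeModel}.
#' @param mode 1-based mode index.
#' @param k number of SDs (default 3).
#' @param dir optional output directory; if given, PLY files are written.
#' @return Invisibly, a list with \code{plus} and \code{minus}
#'   \code{FemurMesh} objects (and \code{files} when written).
#' @export
exportModeMeshes <- function(model, mode = 1L, k = 3, dir = NULL) {
    tmpl <- model@template
    mk <- function(sgn) {
        x <- reconstructShape(
            ifelse(seq_len(ncol(model@modes)) == mode,
                   sgn * k * model@sdev[mode], 0), model)
        V <- vectorToCoords(x)
        new("FemurMesh", vertices = V, faces = tmpl@faces,
            normals = vertexNormals(V, tmpl@faces), axes = tmpl@axes,
            metadata = tmpl@metadata)
    }
    out <- list(plus = mk(1), minus = mk(-1))
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        fp <- file.path(dir, sprintf("mode%d_plus%gsd.ply", mode, k))
        fm <- file.path(dir, sprintf("mode%d_minus%gsd.ply", mode, k))
        writePLY(out$plus, fp)
        writePLY(out$minus, fm)
        out$files <- c(fp, fm)
    }
    invisible(out)
}
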