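#' @import methods
#' @importFrom stats approx coef cor dist fitted lm median na.omit optim
#'   pf pnorm predict qf qnorm quantile residuals rnorm runif sd setNames
#'   spline splinefun var dnorm rlnorm model.matrix
#' @importFrom utils head read.csv tail write.csv capture.output packageVersion
#' @importFrom tools md5sum
#' @useDynLib boneSPM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Triangulated proximal-femur surface
#'
#' A triangle mesh with vertex coordinates in millimetres, outward unit
#' vertex normals and a set of labelled anatomical axes (unit vectors in the
#' mesh frame, e.g. \code{proximalDistal}).  The canonical femur used
#' throughout the package is a \code{FemurMesh} with 5580 vertices; see
#' \code{\link{canonicalFemur}}.
#'
#' @slot vertices numeric matrix, n x 3, mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot normals numeric matrix, n x 3, outward unit normals.
#' @slot axes named list of unit 3-vectors labelling anatomical directions.
#' @slot metadata list of free-form annotations.
#' @export
setClass("FemurMesh",
    representation(vertices = "matrix", faces = "matrix", normals = "matrix",
                   axes = "list", metadata = "list"),
    prototype(axes = list(), metadata = list()))

setValidity("FemurMesh", function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
    if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
    if (nrow(f) && (min(f) < 1L || max(f) > nrow(v)))
        return("face indices out of range")
    if (nrow(object@normals) && nrow(object@normals) != nrow(v))
        return("normals must match vertices")
    TRUE
})

#' Point-based statistical shape model
#'
#' Mean shape, orthonormal modes of variation, per-mode standard deviations
#' (square roots of the eigenvalues, mm), variance fractions and per-subject
#' coefficients, from PCA of concatenated registered vertex coordinates.
#'
#' @slot mean numeric vector, 3n concatenated mean coordinates (mm).
#' @slot modes numeric matrix, 3n x k, orthonormal columns.
#' @slot sdev numeric vector, k, per-mode SD in mm (sqrt eigenvalues).
#' @slot varianceFraction numeric vector, k, fractions of total variance.
#' @slot scores numeric matrix, subjects x k, raw coefficients in mm.
#' @slot template \code{FemurMesh} giving topology/axes for the mean shape.
#' @export
setClass("ShapeModel",
    representation(mean = "numeric", modes = "matrix", sdev = "numeric",
                   varianceFraction = "numeric", scores = "matrix",
                   template = "FemurMesh"))

setValidity("ShapeModel", function(object) {
    k <- ncol(object@modes)
    if (length(object@sdev) != k) return("sdev length must match modes")
    if (length(object@varianceFraction) != k)
        return("varianceFraction length must match modes")
    if (length(object@mean) != nrow(object@modes))
        return("mean length must match mode rows")
    if (ncol(object@scores) && ncol(object@scores) != k)
        return("score columns must match modes")
    TRUE
})

#' Per-vertex blurred-cortex model fit
#'
#' Parameters of the three-level blurred density model at one vertex:
#' outside density \code{y0}, cortical density \code{y1} (CBMD), trabecular
#' density \code{y2} (all mg/cm^3), cortex boundaries \code{x0 < x1} (mm
#' along the outward normal), imaging blur \code{sigma} (mm) and the RMS
#' residual of the fit (mg/cm^3).
#'
#' @export
setClass("CorticalFit",
    representation(y0 = "numeric", y1 = "numeric", y2 = "numeric",
                   x0 = "numeric", x1 = "numeric", sigma = "numeric",
                   residual = "numeric", converged = "logical"),
    prototype(converged = TRUE))

setValidity("CorticalFit", function(object) {
    if (length(object@sigma) && any(object@sigma <= 0, na.rm = TRUE))
        return("sigma must be positive")
    if (length(object@x0) && any(object@x1 <= object@x0, na.rm = TRUE))
        return("x1 must exceed x0")
    TRUE
})

#' Per-vertex cortical map
#'
#' Cortical thickness (cm), cortical bone mineral density (mg/cm^3) and
#' cortical mass surface density (mg/cm^2, always the product of the first
#' two) at every vertex of a mesh, with a per-vertex quality flag.
#'
#' @slot cth,cbmd,cmsd numeric vectors, one value per vertex (NA if flagged).
#' @slot flag logical vector, TRUE where the fit was rejected.
#' @slot mesh the \code{FemurMesh} the values live on.
#' @export
setClass("CorticalMap",
    representation(cth = "numeric", cbmd = "numeric", cmsd = "numeric",
                   flag = "logical", mesh = "FemurMesh"))

setValidity("CorticalMap", function(object) {
    n <- nrow(object@mesh@vertices)
    if (length(object@cth) != n || length(object@cbmd) != n ||
        length(object@cmsd) != n || length(object@flag) != n)
        return("field lengths must match mesh vertex count")
    ok <- !object@flag & !is.na(object@cth) & !is.na(object@cbmd)
    if (any(ok) && max(abs(object@cmsd[ok] - object@cth[ok] *
                           object@cbmd[ok])) > 1e-6)
        return("cmsd must equal cth * cbmd wherever both are defined")
    TRUE
})

#' Canonical-to-individual surface correspondence
#'
#' For each canonical vertex: the matched position on the individual surface,
#' the individual triangle it falls in with convex barycentric weights, and
#' the residual point-to-surface distance.
#'
#' @export
setClass("Correspondence",
    representation(deformed = "matrix", triangle = "integer",
                   bary = "matrix", residual = "numeric",
                   roughness = "numeric", rigid = "list"),
    prototype(roughness = NA_real_))

setValidity("Correspondence", function(object) {
    if (nrow(object@bary) &&
        (min(object@bary) < -1e-8 ||
         max(abs(rowSums(object@bary) - 1)) > 1e-6))
        return("barycentric weights must be convex")
    TRUE
})

#' Vertex-wise GLM / SPM result
#'
#' Ordinary-least-squares fit of one design matrix to a subjects x vertices
#' response matrix, with the F-map for a tested contrast, the percent-per-SD
#' effect map, and (after \code{\link{correctedPMaps}}) family-wise-corrected
#' peak p-values and a cluster table.
#'
#' @slot design numeric design matrix (subjects x p).
#' @slot coef numeric p x vertices coefficient matrix.
#' @slot sigma numeric per-vertex residual SD.
#' @slot df numeric length-2 (df1 placeholder, residual df).
#' @slot Y the response matrix (kept for permutation inference).
#' @slot Fmap,effect numeric per-vertex maps (may be length 0 before computed).
#' @slot contrast integer indices of tested design columns.
#' @slot peakP numeric per-vertex corrected p (length 0 before inference).
#' @slot clusters data.frame cluster table.
#' @slot clusterId integer per-vertex cluster membership (0 = none).
#' @slot mesh the canonical \code{FemurMesh}.
#' @slot method character, inference method used.
#' @export
setClass("SpmFit",
    representation(design = "matrix", coef = "matrix", sigma = "numeric",
                   df = "numeric", Y = "matrix", Fmap = "numeric",
                   effect = "numeric", contrast = "integer",
                   peakP = "numeric", clusters = "data.frame",
                   clusterId = "integer", mesh = "FemurMesh",
                   method = "character"),
    prototype(method = "none", clusters = data.frame()))

#' Named vertex patch on the canonical mesh
#'
#' @slot indices integer vertex indices (1-based, edge-connected).
#' @slot name character label.
#' @slot provenance character, \code{"fixture"} or
#'   \code{"derived-from-cluster"}.
#' @export
setClass("Patch",
    representation(indices = "integer", name = "character",
                   provenance = "character"),
    prototype(provenance = "fixture"))

setValidity("Patch", function(object) {
    if (!length(object@indices)) return("patch must be non-empty")
    if (any(object@indices < 1L)) return("indices must be positive")
    TRUE
})

#' Stack of intensity profiles
#'
#' CT-style calibrated density profiles sampled along the outward normal at
#' every vertex: a common position grid (mm, 0 at the nominal periosteal
#' surface) and a vertices x samples value matrix (mg/cm^3).
#'
#' @export
setClass("IntensityProfiles",
    representation(positions = "numeric", values = "matrix",
                   imaging = "list"))

setValidity("IntensityProfiles", function(object) {
    p <- object@positions
    if (length(p) < 20L) return("need at least 20 samples")
    d <- diff(p)
    if (any(d <= 0)) return("positions must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-8) return("positions must be uniform")
    if (ncol(object@values) != length(p))
        return("value columns must match positions")
    TRUE
})
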