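# Vertex-wise GLM fitting and family-wise-corrected statistical
# parametric mapping on the canonical surface.

#' Build a design matrix for the vertex-wise GLM
#'
#' Assembles the covariate matrix for one of the model specifications
#' used in the analysis ledger:
#' \describe{
#'   \item{\code{"selected"}}{intercept + S0 + Age + S1..S5 + Site -- the
#'     final model: size, age, nonrigid shape and scanning site.}
#'   \item{\code{"exploration-height"}}{intercept + Height + Age + Weight
#'     + S1..S5 + Site -- the a-priori plan, with height in place of
#'     size.}
#'   \item{\code{"exploration-weight"}}{intercept + S0 + Age + Weight +
#'     S1..S5 + Site.}
#' }
#' Shape coefficients enter SD-standardised (so effects read as percent
#' per SD), age is centred, and site enters as treatment-coded dummies
#' with the alphabetically first label as reference.  Zero-variance
#' columns are dropped with a warning; rank deficiency is an error naming
#' the dependent columns.  The pairwise correlations among non-intercept
#' columns (the collinearity audit that motivates keeping height out of
#' the selected model) are attached as \code{attr(, "correlations")}.
#'
#' @param cohort cohort table with \code{age}, \code{weight},
#'   \code{height}, \code{site}.
#' @param scores subjects x modes matrix of SD-standardised shape
#'   coefficients (e.g. \code{scores(model, standardized = TRUE)}).
#' @param spec model specification name.
#' @param nShapeModes how many nonrigid modes (S1...) to adjust for.
#' @return Numeric design matrix with attributes \code{"contrast"} (the
#'   tested column indices) and \code{"correlations"}.
#' @export
buildDesign <- function(cohort, scores,
                        spec = c("selected", "exploration-height",
                                 "exploration-weight"),
                        nShapeModes = 5L) {
    spec <- match.arg(spec)
    n <- nrow(cohort)
    stopifnot(nrow(scores) == n)
    shp <- scores[, 1L + seq_len(min(nShapeModes, ncol(scores) - 1L)),
                  drop = FALSE]
    colnames(shp) <- paste0("S", seq_len(ncol(shp)))
    ageC <- cohort$age - mean(cohort$age)
    site <- droplevels(factor(cohort$site))
    siteCols <- NULL
    if (nlevels(site) > 1L) {
        mm <- model.matrix(~site)
        siteCols <- mm[, -1L, drop = FALSE]
        colnames(siteCols) <- sub("^site", "Site", colnames(siteCols))
    } else {
        warning("single site: site columns dropped")
    }
    base <- switch(spec,
        "selected" = cbind(S0 = scores[, 1], Age = ageC, shp),
        "exploration-height" = cbind(Hgt = cohort$height, Age = ageC,
                                     Wgt = cohort$weight, shp),
        "exploration-weight" = cbind(S0 = scores[, 1], Age = ageC,
                                     Wgt = cohort$weight, shp))
    X <- cbind(Intercept = 1, base, siteCols)
    keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, sd) > 1e-12)
    if (!all(keep)) {
        warning("dropping zero-variance columns: ",
                paste(colnames(X)[!keep], collapse = ", "))
        X <- X[, keep, drop = FALSE]
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("design is rank deficient; dependent columns: ",
             paste(dep, collapse = ", "))
    }
    if (n < ncol(X) + 10L)
        warning("fewer than p + 10 subjects for p = ", ncol(X),
                " columns")
    contrastName <- if (spec == "exploration-height") "Hgt" else "S0"
    attr(X, "contrast") <- which(colnames(X) == contrastName)
    attr(X, "correlations") <- cor(X[, -1L, drop = FALSE])
    attr(X, "spec") <- spec
    X
}

#' Fit the vertex-wise GLM
#'
#' Ordinary least squares of every vertex column of Y against one shared
#' design matrix, via a single QR decomposition.
#'
#' @param design design matrix (subjects x p), e.g. from
#'   \code{\link{buildDesign}}.
#' @param Y response matrix, subjects x vertices.
#' @param mesh the canonical mesh (for cluster connectivity later).
#' @return An \code{\linkS4class{SpmFit}} with coefficients, residual SD
#'   and residual degrees of freedom.
#' @export
fitGlm <- function(design, Y, mesh = canonicalFemur()) {
    design <- as.matrix(design)
    Y <- as.matrix(Y)
    stopifnot(nrow(design) == nrow(Y))
    if (anyNA(Y)) {
        bad <- colSums(is.na(Y))
        stop("Y contains missing values at ", sum(bad > 0),
             " vertices; impute or drop subjects first")
    }
    n <- nrow(design); p <- ncol(design)
    df2 <- n - p
    if (df2 <= 0) stop("non-positive residual degrees of freedom")
    qrX <- qr(design)
    B <- qr.coef(qrX, Y)
    res <- Y - design %*% B
    sigma <- sqrt(colSums(res^2) / df2)
    new("SpmFit", design = design, coef = B, sigma = sigma,
        df = c(NA_real_, df2), Y = Y,
        contrast = attr(design, "contrast") %||% integer(),
        mesh = mesh, method = "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' F-test on a column subset
#'
#' Nested-model F from residual sums of squares: the full model against
#' the model with the contrast columns removed.  Equals the squared t
#' statistic for single-column contrasts.
#'
#' @param fit an \code{\linkS4class{SpmFit}}.
#' @param contrast integer column indices to test (default: the design's
#'   stored contrast).
#' @return The fit, with \code{Fmap} and \code{df} filled in.
#' @export
fTest <- function(fit, contrast = NULL) {
    if (is.null(contrast)) contrast <- fit@contrast
    stopifnot(length(contrast) >= 1L,
              all(contrast %in% seq_len(ncol(fit@design))))
    X <- fit@design
    Y <- fit@Y
    q <- length(contrast)
    df2 <- fit@df[2]
    rssF <- colSums((Y - X %*% fit@coef)^2)
    Xr <- X[, -contrast, drop = FALSE]
    Br <- qr.coef(qr(Xr), Y)
    rssR <- colSums((Y - Xr %*% Br)^2)
    Fv <- pmax(0, (rssR - rssF) / q) / (rssF / df2)
    fit@Fmap <- as.vector(Fv)
    fit@df <- c(q, df2)
    fit@contrast <- as.integer(contrast)
    fit
}

#' Percent-change effect map
#'
#' Converts the tested coefficient into percent change of the outcome per
#' unit of the (SD-standardised) covariate:
#' \code{100 * beta / y_ref}, where \code{y_ref} is the model prediction
#' at cohort-mean covariates and the reference site (site dummies zero).
#' Vertices with non-positive reference prediction are masked.
#'
#' @param fit an \code{SpmFit} whose contrast is a single column.
#' @return The fit with the \code{effect} slot filled in.
#' @export
effectPercentMap <- function(fit) {
    stopifnot(length(fit@contrast) == 1L)
    X <- fit@design
    xref <- colMeans(X)
    siteCols <- grep("^Site", colnames(X))
    xref[siteCols] <- 0
    yref <- as.vector(xref %*% fit@coef)
    eff <- 100 * fit@coef[fit@contrast, ] / yref
    eff[yref <= 0] <- NA_real_
    fit@effect <- as.vector(eff)
    fit
}

# connected components of the supra-threshold vertex set; returns sizes
# and a per-vertex component id
.clusterComponents <- function(supra, graph) {
    idx <- which(supra)
    out <- list(sizes = integer(), id = integer(length(supra)))
    if (!length(idx)) return(out)
    sg <- igraph::induced_subgraph(graph, idx)
    comp <- igraph::components(sg)
    out$sizes <- as.integer(comp$csize)
    out$id[idx] <- comp$membership
    out
}

#' Family-wise-corrected p-maps
#'
#' Computes multiple-comparison-corrected p-values for the F-map over the
#' surface, by vertex peak magnitude and by the extent of connected
#' clusters above an uncorrected cluster-forming threshold (p = 0.001 by
#' default).  Two methods:
#' \describe{
#'   \item{\code{"permutation"} (default)}{Freedman-Lane residual
#'     permutation: residuals of the reduced model (contrast columns
#'     removed) are permuted over subjects, the full model is refitted,
#'     and the null distributions of the image-wise maximum F and maximum
#'     cluster extent control the family-wise error exactly under
#'     exchangeability.}
#'   \item{\code{"rft"}}{random-field-theory expected-Euler-characteristic
#'     approximation for F fields on the 2D surface, using residual-based
#'     smoothness estimation; provided for fidelity to the classical SPM
#'     route but approximate on irregular meshes.}
#' }
#'
#' @param fit an \code{SpmFit} with \code{Fmap} computed.
#' @param clusterAlpha uncorrected cluster-forming p threshold.
#' @param method \code{"permutation"} or \code{"rft"}.
#' @param nPerm number of permutations (at least 100).
#' @param seed integer seed for the permutation stream.
#' @param graph optional precomputed mesh graph.
#' @return The fit with \code{peakP}, \code{clusters} (data.frame: id,
#'   extent, pPeakMin, pCorrected, centroid coordinates) and
#'   \code{clusterId} filled in; \code{method} records the route.
#' @export
correctedPMaps <- function(fit, clusterAlpha = 0.001,
                           method = c("permutation", "rft"),
                           nPerm = 1000L, seed = 1L, graph = NULL) {
    method <- match.arg(method)
    stopifnot(length(fit@Fmap) > 0)
    if (is.null(graph)) graph <- meshGraph(fit@mesh)
    q <- fit@df[1]; df2 <- fit@df[2]
    fCrit <- qf(1 - clusterAlpha, q, df2)
    obs <- .clusterComponents(fit@Fmap > fCrit, graph)
    if (method == "permutation") {
        if (nPerm < 100L) stop("need at least 100 permutations")
        X <- fit@design; Y <- fit@Y
        n <- nrow(X)
        Xr <- X[, -fit@contrast, drop = FALSE]
        qrR <- qr(Xr)
        fitR <- qr.fitted(qrR, Y)
        resR <- Y - fitR
        qrF <- qr(X)
        QF <- qr.Q(qrF)
        QR <- qr.Q(qrR)
        set.seed(childSeed(seed, 8L))
        maxF <- numeric(nPerm)
        maxExt <- numeric(nPerm)
        for (b in seq_len(nPerm)) {
            Yb <- fitR + resR[sample.int(n), , drop = FALSE]
            tot <- colSums(Yb^2)
            rssF <- tot - colSums(crossprod(QF, Yb)^2)
            rssR <- tot - colSums(crossprod(QR, Yb)^2)
            Fb <- pmax(0, (rssR - rssF) / q) / (rssF / df2)
            maxF[b] <- max(Fb)
            cl <- .clusterComponents(Fb > fCrit, graph)
            maxExt[b] <- if (length(cl$sizes)) max(cl$sizes) else 0
        }
        fit@peakP <- vapply(fit@Fmap, function(f)
            (1 + sum(maxF >= f)) / (nPerm + 1), 0)
        pExt <- vapply(obs$sizes, function(s)
            (1 + sum(maxExt >= s)) / (nPerm + 1), 0)
    } else {
        rft <- .rftCorrection(fit, fCrit, clusterAlpha)
        fit@peakP <- rft$peakP
        pExt <- vapply(obs$sizes, rft$clusterP, 0)
    }
    fit@clusterId <- as.integer(obs$id)
    if (length(obs$sizes)) {
        cent <- t(vapply(seq_along(obs$sizes), function(k) {
            v <- which(obs$id == k)
            colMeans(fit@mesh@vertices[v, , drop = FALSE])
        }, numeric(3)))
        fit@clusters <- data.frame(
            id = seq_along(obs$sizes), extent = obs$sizes,
            pPeakMin = vapply(seq_along(obs$sizes), function(k)
                min(fit@peakP[obs$id == k]), 0),
            pCorrected = pExt,
            x = cent[, 1], y = cent[, 2], z = cent[, 3])
        fit@clusters <- fit@clusters[order(fit@clusters$pCorrected,
                                           -fit@clusters$extent), ,
                                     drop = FALSE]
    } else {
        fit@clusters <- data.frame(id = integer(), extent = integer(),
                                   pPeakMin = numeric(),
                                   pCorrected = numeric(),
                                   x = numeric(), y = numeric(),
                                   z = numeric())
    }
    fit@method <- method
    fit
}

# Random-field-theory approximation: EC densities for an F field
# (Worsley 1994) on a 2D surface, with resels from residual smoothness.
.rftCorrection <- function(fit, fCrit, clusterAlpha) {
    mesh <- fit@mesh
    k <- fit@df[1]; v <- fit@df[2]
    # normalised residuals and roughness -> FWHM estimate per edge
    res <- fit@Y - fit@design %*% fit@coef
    sd0 <- sqrt(colSums(res^2))
    sd0[sd0 == 0] <- 1
    e <- sweep(res, 2L, sd0, "/")
    ed <- meshEdges(mesh)
    len <- sqrt(rowSums((mesh@vertices[ed[, 1], ] -
                         mesh@vertices[ed[, 2], ])^2))
    du2 <- colSums((e[, ed[, 1], drop = FALSE] -
                    e[, ed[, 2], drop = FALSE])^2)
    lambda <- mean(du2 / len^2)            # mean squared gradient
    fwhm <- sqrt(4 * log(2) / max(lambda, 1e-12))
    area <- sum(vertexAreas(mesh))
    nV <- nrow(mesh@vertices); nE <- nrow(ed); nF <- nrow(mesh@faces)
    R0 <- nV - nE + nF                      # Euler characteristic
    R2 <- area / fwhm^2
    R1 <- 0.5 * sum(len) / fwhm / sqrt(pi)  # rough 1-resel count
    ec <- function(f) {
        t1 <- k * f / v
        a <- 4 * log(2); b <- lgamma(v / 2) + lgamma(k / 2)
        ec0 <- pf(f, k, v, lower.tail = FALSE)
        ec1 <- sqrt(a) / (2 * pi) * exp(lgamma((v + k - 1) / 2) - b) *
            sqrt(2) * t1^((k - 1) / 2) * (1 + t1)^(-(v + k - 2) / 2)
        ec2 <- a / (2 * pi) * exp(lgamma((v + k - 2) / 2) - b) *
            t1^((k - 2) / 2) * (1 + t1)^(-(v + k - 2) / 2) *
            ((v - 1) * t1 - (k - 1))
        c(ec0, ec1, ec2)
    }
    peakP <- vapply(fit@Fmap, function(f) {
        d <- ec(f)
        min(1, max(0, R0 * d[1] + R1 * d[2] + R2 * d[3]))
    }, 0)
    # cluster-extent correction via the expected cluster count and size
    Em <- max(1e-12, sum(ec(fCrit) * c(R0, R1, R2)))
    p0 <- pf(fCrit, k, v, lower.tail = FALSE)
    En <- nrow(mesh@vertices) * p0 / Em     # expected size in vertices
    clusterP <- function(s) {
        beta <- (gamma(2) / En)             # 2D: P(n>=s) = exp(-beta s)
        pn <- exp(-beta * s)
        min(1, max(0, 1 - exp(-Em * pn)))
    }
    list(peakP = peakP, clusterP = clusterP, fwhm = fwhm,
         resels = c(R0, R1, R2))
}
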