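#' Accessors for boneSPM classes
#'
#' Small accessor generics in the Bioconductor style: \code{vertices},
#' \code{faces}, \code{normals}, \code{meshAxes} for meshes;
#' \code{shapeModes}, \code{shapeMean}, \code{modeSD}, \code{varianceFraction},
#' \code{scores} for shape models; \code{cth}, \code{cbmd}, \code{cmsd} for
#' cortical maps; \code{patchIndices} for patches.
#'
#' @param object an object of the documented class.
#' @param standardized logical; for \code{scores}, divide each column by the
#'   mode SD so coefficients are in SD units.
#' @return The slot contents (see slot documentation of each class).
#' @name accessors
#' @aliases vertices faces normals meshAxes shapeModes shapeMean modeSD
#'   varianceFraction scores cth cbmd cmsd patchIndices
#' @examples
#' mesh <- canonicalFemur()
#' dim(vertices(mesh))
#' length(patchIndices(defaultNeckPatch()))
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("normals", function(object) standardGeneric("normals"))
#' @rdname accessors
#' @export
setGeneric("meshAxes", function(object) standardGeneric("meshAxes"))
#' @rdname accessors
#' @export
setGeneric("shapeModes", function(object) standardGeneric("shapeModes"))
#' @rdname accessors
#' @export
setGeneric("shapeMean", function(object) standardGeneric("shapeMean"))
#' @rdname accessors
#' @export
setGeneric("modeSD", function(object) standardGeneric("modeSD"))
#' @rdname accessors
#' @export
setGeneric("varianceFraction",
           function(object) standardGeneric("varianceFraction"))
#' @rdname accessors
#' @export
setGeneric("scores",
           function(object, standardized = FALSE) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("cth", function(object) standardGeneric("cth"))
#' @rdname accessors
#' @export
setGeneric("cbmd", function(object) standardGeneric("cbmd"))
#' @rdname accessors
#' @export
setGeneric("cmsd", function(object) standardGeneric("cmsd"))
#' @rdname accessors
#' @export
setGeneric("patchIndices", function(object) standardGeneric("patchIndices"))

#' @rdname accessors
setMethod("vertices", "FemurMesh", function(object) object@vertices)
#' @rdname accessors
setMethod("faces", "FemurMesh", function(object) object@faces)
#' @rdname accessors
setMethod("normals", "FemurMesh", function(object) object@normals)
#' @rdname accessors
setMethod("meshAxes", "FemurMesh", function(object) object@axes)
#' @rdname accessors
setMethod("shapeModes", "ShapeModel", function(object) object@modes)
#' @rdname accessors
setMethod("shapeMean", "ShapeModel", function(object) object@mean)
#' @rdname accessors
setMethod("modeSD", "ShapeModel", function(object) object@sdev)
#' @rdname accessors
setMethod("varianceFraction", "ShapeModel",
          function(object) object@varianceFraction)
#' @rdname accessors
setMethod("scores", "ShapeModel", function(object, standardized = FALSE) {
    s <- object@scores
    if (standardized) {
        sdev <- ifelse(object@sdev > 0, object@sdev, 1)
        s <- sweep(s, 2L, sdev, "/")
    }
    s
})
#' @rdname accessors
setMethod("cth", "CorticalMap", function(object) object@cth)
#' @rdname accessors
setMethod("cbmd", "CorticalMap", function(object) object@cbmd)
#' @rdname accessors
setMethod("cmsd", "CorticalMap", function(object) object@cmsd)
#' @rdname accessors
setMethod("patchIndices", "Patch", function(object) object@indices)

setMethod("show", "FemurMesh", function(object) {
    cat("FemurMesh with", nrow(object@vertices), "vertices and",
        nrow(object@faces), "faces\n")
    bb <- apply(object@vertices, 2L, range)
    cat(sprintf("  extent (mm): x %.1f  y %.1f  z %.1f\n",
                diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3])))
    if (length(object@axes))
        cat("  axes:", paste(names(object@axes), collapse = ", "), "\n")
})

setMethod("show", "ShapeModel", function(object) {
    k <- ncol(object@modes)
    cat("ShapeModel:", nrow(object@scores), "subjects,", k, "modes over",
        length(object@mean), "coordinates\n")
    nshow <- min(k, 5L)
    cat("  variance fractions (%):",
        paste(sprintf("%.1f", 100 * object@varianceFraction[seq_len(nshow)]),
              collapse = " "),
        if (k > nshow) "...\n" else "\n")
})

setMethod("show", "CorticalMap", function(object) {
    ok <- !object@flag
    cat("CorticalMap on", length(object@cth), "vertices;",
        sprintf("coverage %.1f%%\n", 100 * mean(ok)))
    if (any(ok))
        cat(sprintf("  CTh %.2f cm  CBMD %.0f mg/cm^3  CMSD %.0f mg/cm^2 (medians)\n",
                    median(object@cth[ok]), median(object@cbmd[ok]),
                    median(object@cmsd[ok])))
})

setMethod("show", "SpmFit", function(object) {
    cat("SpmFit:", nrow(object@design), "subjects x",
        ncol(object@coef), "vertices;", ncol(object@design),
        "design columns\n")
    if (length(object@Fmap))
        cat(sprintf("  max F = %.2f (df %d, %d); inference: %s\n",
                    max(object@Fmap), length(object@contrast),
                    as.integer(object@df[2]), object@method))
    if (nrow(object@clusters))
        cat("  clusters:", nrow(object@clusters), "significant at p<0.05\n")
})

setMethod("show", "Patch", function(object) {
    cat(sprintf("Patch '%s' (%s): %d vertices\n", object@name,
                object@provenance, length(object@indices)))
})

setMethod("show", "IntensityProfiles", function(object) {
    cat("IntensityProfiles:", nrow(object@values), "profiles,",
        length(object@positions), "samples, spacing",
        sprintf("%.2f mm\n", diff(object@positions[1:2])))
})

setMethod("show", "Correspondence", function(object) {
    cat("Correspondence over", nrow(object@deformed), "canonical vertices;",
        sprintf("mean residual %.3f mm\n", mean(object@residual)))
})
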