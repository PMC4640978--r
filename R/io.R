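# Plain-text mesh, table and volume I/O.

#' Write / read a mesh as ASCII PLY
#'
#' Standard Stanford PLY (ASCII 1.0) with optional per-vertex scalar
#' properties.  Coordinates are written at micrometre precision.
#'
#' @param mesh a \code{FemurMesh}.
#' @param path output file.
#' @param scalars optional named list of per-vertex numeric vectors,
#'   written as extra float vertex properties.
#' @return \code{path}, invisibly.
#' @export
writePLY <- function(mesh, path, scalars = NULL) {
    v <- mesh@vertices; f <- mesh@faces
    props <- c("property float x", "property float y", "property float z")
    cols <- v
    for (nm in names(scalars)) {
        props <- c(props, paste("property float", nm))
        cols <- cbind(cols, scalars[[nm]])
    }
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)), props,
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    write.table(format(cols, trim = TRUE, digits = 7, scientific = FALSE),
                con, row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writePLY
#' @param axes axis labels to attach to the mesh read back.
#' @export
readPLY <- function(path, axes = list()) {
    lines <- readLines(path)
    endH <- which(lines == "end_header")[1]
    hdr <- lines[seq_len(endH)]
    nV <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", hdr, value = TRUE)))
    nF <- as.integer(sub("element face ", "",
                         grep("^element face", hdr, value = TRUE)))
    propNames <- sub("^property float ", "",
                     grep("^property float", hdr, value = TRUE))
    vdat <- read.table(text = lines[endH + seq_len(nV)])
    names(vdat) <- propNames
    fdat <- read.table(text = lines[endH + nV + seq_len(nF)])
    mesh <- FemurMesh(unname(as.matrix(vdat[, c("x", "y", "z")])),
                      unname(as.matrix(fdat[, 2:4])) + 1L, axes = axes)
    extra <- setdiff(propNames, c("x", "y", "z"))
    if (length(extra)) mesh@metadata$scalars <- vdat[extra]
    mesh
}

#' Write a mesh with per-vertex scalar fields as legacy VTK polydata
#'
#' ASCII legacy VTK, with any number of per-vertex SCALARS arrays --
#' the standard interchange for surface overlays (effect maps, F-maps,
#' -log10 p maps).
#'
#' @param mesh a \code{FemurMesh}.
#' @param path output file.
#' @param scalars named list of per-vertex numeric vectors.
#' @return \code{path}, invisibly.
#' @export
writeVTK <- function(mesh, path, scalars = NULL) {
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "surface with overlays",
                 "ASCII", "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "float")), con)
    write.table(format(v, trim = TRUE, digits = 7), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(paste("POLYGONS", nrow(f), 4 * nrow(f)), con)
    write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    if (length(scalars)) {
        writeLines(paste("POINT_DATA", nrow(v)), con)
        for (nm in names(scalars)) {
            writeLines(c(paste("SCALARS", nm, "float 1"),
                         "LOOKUP_TABLE default"), con)
            s <- scalars[[nm]]
            s[is.na(s)] <- -9999
            writeLines(format(s, trim = TRUE, digits = 7), con)
        }
    }
    invisible(path)
}

#' Write a phantom volume as NIfTI-1
#'
#' Requires the \pkg{RNifti} package; mm voxel spacing is recorded in the
#' header.
#'
#' @param phantom result of \code{\link{rasterizePhantomVolume}}.
#' @param path output .nii / .nii.gz file.
#' @return \code{path}, invisibly.
#' @export
writeVolumeNifti <- function(phantom, path) {
    if (!requireNamespace("RNifti", quietly = TRUE))
        stop("RNifti is required to write NIfTI volumes")
    img <- RNifti::asNifti(phantom$volume,
                           pixdim = rep(phantom$voxel, 3))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write cohort tables
#'
#' Plain CSV with a header row; factors restored for \code{site}.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return \code{readCohort}: the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
    write.csv(cohort, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    out <- read.csv(path, stringsAsFactors = FALSE)
    out$site <- factor(out$site)
    out
}
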