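# End-to-end orchestration, patch-level quantification and the model
# ledger.

#' Construct a Patch
#'
#' @param indices integer vertex indices on the canonical mesh.
#' @param name label.
#' @param provenance \code{"fixture"} or \code{"derived-from-cluster"}.
#' @return A \code{\linkS4class{Patch}}.
#' @export
Patch <- function(indices, name = "patch", provenance = "fixture") {
    new("Patch", indices = as.integer(sort(unique(indices))), name = name,
        provenance = provenance)
}

#' The default femoral neck patch
#'
#' The frozen superior-femoral-neck vertex set used for patch-level effect
#' quantification, shipped as a plain-text fixture.  It is the
#' morphological core (a 3-ring erosion) of the generator's planted
#' superior-neck region on the canonical mesh, mirroring how a focal
#' quantification region is frozen from a detected cluster: a cluster
#' detected by thresholded statistics sits inside the true lesion, and
#' using the core avoids edge attenuation from surface smoothing.
#'
#' @return A \code{\linkS4class{Patch}}.
#' @examples
#' length(patchIndices(defaultNeckPatch()))
#' @export
defaultNeckPatch <- function() {
    f <- system.file("extdata", "default_neck_patch.txt",
                     package = "boneSPM")
    if (!nzchar(f)) stop("patch fixture not found")
    idx <- scan(f, what = integer(), comment.char = "#", quiet = TRUE)
    Patch(idx, name = "default femoral neck patch",
          provenance = "fixture")
}

#' Run configuration
#'
#' Assembles and validates the configuration for
#' \code{\link{runPipeline}}.  All arguments have working defaults; a
#' YAML file with the same keys can be loaded with
#' \code{\link{readRunConfig}}.
#'
#' @param preset \code{"male"}, \code{"female"}, \code{"null"} or a
#'   preset list from \code{\link{malePreset}} and friends.
#' @param n optional cohort-size override.
#' @param seed root seed; every stage derives its own stream from it.
#' @param route \code{"field"} (true cortical fields pass the imaging
#'   stage) or \code{"image"} (profiles are synthesised and refitted by
#'   cortical bone mapping).
#' @param registration logical; FALSE short-circuits registration with
#'   the identity correspondence (for reduced-scale statistical
#'   experiments).
#' @param pose logical; apply random scanner-pose perturbations.
#' @param smoothingFWHM surface smoothing FWHM in mm.
#' @param model GLM specification (see \code{\link{buildDesign}}).
#' @param inference \code{"none"}, \code{"permutation"} or \code{"rft"}.
#' @param nPerm permutations for permutation inference.
#' @param clusterAlpha cluster-forming uncorrected p threshold.
#' @param nShapeModes nonrigid modes adjusted for in the GLM.
#' @param outcomes which outcome maps to analyse.
#' @param imageVertices optional vertex subset for the image route.
#' @param globalSubsample vertices used for each subject's global CBM
#'   stage (image route).
#' @param outdir optional output directory for artifacts + manifest.
#' @param verbose logical.
#' @return A validated config list (class \code{"RunConfig"}).
#' @export
runConfig <- function(preset = "male", n = NULL, seed = 20150601,
                      route = c("field", "image"), registration = TRUE,
                      pose = TRUE, smoothingFWHM = 6,
                      model = "selected",
                      inference = c("none", "permutation", "rft"),
                      nPerm = 1000L, clusterAlpha = 0.001,
                      nShapeModes = 5L,
                      outcomes = c("cmsd", "cth", "cbmd"),
                      imageVertices = NULL, globalSubsample = 300L,
                      outdir = NULL, verbose = FALSE) {
    route <- match.arg(route)
    inference <- match.arg(inference)
    if (is.character(preset))
        preset <- switch(match.arg(preset, c("male", "female", "null")),
                         male = if (is.null(n)) malePreset() else
                             malePreset(n = n),
                         female = if (is.null(n)) femalePreset() else
                             femalePreset(n = n),
                         null = if (is.null(n)) nullPreset() else
                             nullPreset(n = n))
    validatePreset(preset)
    stopifnot(is.numeric(seed), length(seed) == 1L,
              smoothingFWHM >= 0, nPerm >= 100L,
              clusterAlpha > 0, clusterAlpha < 1,
              all(outcomes %in% c("cmsd", "cth", "cbmd")))
    structure(list(preset = preset, seed = as.integer(seed),
                   route = route, registration = registration,
                   pose = pose, smoothingFWHM = smoothingFWHM,
                   model = model, inference = inference,
                   nPerm = as.integer(nPerm),
                   clusterAlpha = clusterAlpha,
                   nShapeModes = as.integer(nShapeModes),
                   outcomes = outcomes, imageVertices = imageVertices,
                   globalSubsample = as.integer(globalSubsample),
                   outdir = outdir, verbose = verbose),
              class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file whose keys are \code{runConfig} arguments.
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    bad <- setdiff(names(vals), names(formals(runConfig)))
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}

#' Run the full analysis pipeline
#'
#' Executes cohort synthesis, shape deformation, true-field generation,
#' (optionally) profile synthesis plus cortical bone mapping, canonical
#' registration, data transfer and smoothing, shape-model construction,
#' the vertex-wise GLM with effect maps, optional family-wise inference,
#' and patch-level quantification -- all driven by one seeded
#' configuration.  Stage timings, seeds and output hashes go into the
#' manifest.
#'
#' @param config a \code{\link{runConfig}} list or path to a YAML file.
#' @return A result bundle (list) with the cohort, the registered-data
#'   \code{SummarizedExperiment} (vertices x subjects; assays cmsd, cth,
#'   cbmd; \code{colData} = demographics + estimated coefficients), the
#'   shape model (mode 1 oriented so +1 SD enlarges the femur), per-
#'   outcome \code{SpmFit} objects, the patch statistics table and the
#'   manifest.
#' @export
runPipeline <- function(config = runConfig()) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    t00 <- Sys.time()
    timings <- c()
    tic <- function() Sys.time()
    toc <- function(t0, nm) {
        timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                                2)
        if (config$verbose) message(nm, ": ", timings[[nm]], "s")
    }
    preset <- config$preset
    mesh <- canonicalFemur()
    region <- plantedRegion(mesh)

    t0 <- tic()
    cohort <- generateCohort(preset, config$seed)
    truth <- plantedShapeModel(preset, mesh)
    toc(t0, "cohort")

    t0 <- tic()
    meshes <- subjectMeshes(cohort, truth, config$seed,
                            pose = config$pose && config$registration,
                            preset = preset)
    toc(t0, "shapes")

    t0 <- tic()
    set.seed(childSeed(config$seed, 3L))
    fieldSeeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
    fields <- lapply(seq_len(nrow(cohort)), function(i)
        generateTrueField(cohort[i, ], preset, patch = region,
                          mesh = mesh, seed = fieldSeeds[i]))
    toc(t0, "fields")

    maps <- fields
    if (config$route == "image") {
        t0 <- tic()
        profs <- lapply(seq_len(nrow(cohort)), function(i)
            synthesizeProfiles(fields[[i]], preset$imaging,
                               seed = fieldSeeds[i],
                               vertices = config$imageVertices))
        cb <- mapCohort(profs, mesh,
                        globalSubsample = config$globalSubsample,
                        verbose = config$verbose)
        if (length(cb$excluded))
            stop("subjects excluded by CBM coverage: ",
                 paste(cb$excluded, collapse = ", "))
        maps <- cb$maps
        toc(t0, "cbm")
    }

    t0 <- tic()
    n <- nrow(cohort)
    excluded <- integer()
    if (config$registration) {
        reg <- suppressWarnings(
            registerCohort(mesh, meshes, verbose = config$verbose))
        # registration quality control: drop subjects whose mean surface
        # residual or displacement roughness marks a failed registration
        keep <- reg$residual <= 0.5 & reg$roughness <= 0.2
        excluded <- which(!keep)
        if (length(excluded)) {
            message("excluding ", length(excluded),
                    " subject(s) on registration quality: ",
                    paste(cohort$subject_id[excluded], collapse = ", "))
            cohort <- cohort[keep, , drop = FALSE]
            meshes <- meshes[keep]
            maps <- maps[keep]
            reg$X <- reg$X[keep, , drop = FALSE]
            reg$correspondences <- reg$correspondences[keep]
            reg$residual <- reg$residual[keep]
            n <- nrow(cohort)
        }
        X <- reg$X
        Yl <- lapply(seq_len(n), function(i)
            transferData(maps[[i]], reg$correspondences[[i]],
                         meshes[[i]]@faces))
        regResidual <- reg$residual
    } else {
        X <- t(vapply(seq_len(n), function(i)
            coordsToVector(deformMesh(mesh,
                as.numeric(cohort[i, grep("^trueS", names(cohort))]),
                truth)@vertices), numeric(3 * nrow(mesh@vertices))))
        Yl <- lapply(maps, function(m)
            cbind(cth = m@cth, cbmd = m@cbmd, cmsd = m@cmsd))
        regResidual <- rep(0, n)
    }
    toc(t0, "registration")

    t0 <- tic()
    assays <- lapply(c(cth = "cth", cbmd = "cbmd", cmsd = "cmsd"),
                     function(f)
        vapply(Yl, function(y) y[, f], numeric(nrow(mesh@vertices))))
    assays <- lapply(assays, smoothSurface, mesh = mesh,
                     fwhm = config$smoothingFWHM)
    toc(t0, "smoothing")

    t0 <- tic()
    model <- buildShapeModel(X, template = mesh)
    model <- orientMode(model, 1L, "proximalDistal")
    toc(t0, "shapeModel")

    t0 <- tic()
    sc <- scores(model, standardized = TRUE)
    design <- buildDesign(cohort, sc, spec = config$model,
                          nShapeModes = config$nShapeModes)
    spm <- lapply(setNames(config$outcomes, config$outcomes),
                  function(oc) {
        ft <- fitGlm(design, t(assays[[oc]]), mesh = mesh)
        ft <- fTest(ft)
        effectPercentMap(ft)
    })
    toc(t0, "glm")

    if (config$inference != "none") {
        t0 <- tic()
        spm$cmsd <- correctedPMaps(spm$cmsd,
                                   clusterAlpha = config$clusterAlpha,
                                   method = config$inference,
                                   nPerm = config$nPerm,
                                   seed = config$seed)
        toc(t0, "inference")
    }

    patch <- defaultNeckPatch()
    patchStats <- data.frame(
        outcome = config$outcomes,
        effectPerSD = vapply(config$outcomes, function(oc)
            patchEffect(spm[[oc]], patch), 0),
        row.names = NULL)

    colData <- S4Vectors::DataFrame(cohort,
                                    S = I(sc[, seq_len(min(6, ncol(sc))),
                                             drop = FALSE]))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = colData,
        metadata = list(smoothingFWHM = config$smoothingFWHM,
                        route = config$route,
                        registrationResidual = regResidual))

    manifest <- list(
        package = as.character(utils::packageVersion("boneSPM")),
        seed = config$seed,
        preset = preset$name, n = n,
        excludedSubjects = length(excluded), route = config$route,
        model = config$model, inference = config$inference,
        smoothingFWHM = config$smoothingFWHM,
        timings = as.list(timings),
        totalSeconds = round(as.numeric(Sys.time() - t00,
                                        units = "secs"), 2))
    out <- list(config = config, cohort = cohort, truthModel = truth,
                X = X, se = se, model = model, spm = spm, patch = patch,
                patchStats = patchStats, manifest = manifest)
    if (!is.null(config$outdir)) .writeBundle(out, config$outdir)
    out
}

# write the standard artifact set + manifest (with file hashes)
.writeBundle <- function(run, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    mesh <- run$model@template
    writeCohort(cbind(run$cohort,
                      setNames(as.data.frame(
                          scores(run$model, standardized = TRUE)[,
                              1:6, drop = FALSE]),
                          paste0("Shat", 0:5))),
                file.path(outdir, "cohort.csv"))
    write.csv(run$patchStats, file.path(outdir, "patch_stats.csv"),
              row.names = FALSE)
    ov <- list(effect = run$spm$cmsd@effect, F = run$spm$cmsd@Fmap)
    if (length(run$spm$cmsd@peakP))
        ov$minusLog10PeakP <- -log10(run$spm$cmsd@peakP)
    writeVTK(mesh, file.path(outdir, "cmsd_maps.vtk"), scalars = ov)
    if (nrow(run$spm$cmsd@clusters))
        write.csv(run$spm$cmsd@clusters,
                  file.path(outdir, "clusters.csv"), row.names = FALSE)
    files <- list.files(outdir, full.names = TRUE)
    run$manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(run$manifest,
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(outdir)
}

#' Patch-level average effect
#'
#' Unweighted mean of the percent-per-SD effect map over the patch
#' vertices.
#'
#' @param spm an \code{SpmFit} with the effect map computed.
#' @param patch a \code{\linkS4class{Patch}}.
#' @return Mean percent change per SD within the patch.
#' @export
patchEffect <- function(spm, patch) {
    stopifnot(length(spm@effect) > 0)
    idx <- patchIndices(patch)
    vals <- spm@effect[idx]
    vals <- vals[is.finite(vals)]
    if (!length(vals))
        stop("patch has no overlap with valid effect-map vertices")
    mean(vals)
}

#' Extract a significant cluster as a Patch
#'
#' Converts the rank-th significant cluster (corrected p < alpha) of an
#' inference-bearing \code{SpmFit} into a \code{Patch} with provenance
#' \code{"derived-from-cluster"}.
#'
#' @param spm an \code{SpmFit} after \code{\link{correctedPMaps}}.
#' @param rank 1-based rank by corrected p then extent.
#' @param alpha significance level.
#' @return A \code{Patch}, or \code{NULL} (with a message) when there is
#'   no significant cluster of that rank.
#' @export
extractClusterPatch <- function(spm, rank = 1L, alpha = 0.05) {
    cl <- spm@clusters
    sig <- cl[cl$pCorrected < alpha, , drop = FALSE]
    if (nrow(sig) < rank) {
        message("no significant cluster at rank ", rank)
        return(NULL)
    }
    id <- sig$id[rank]
    Patch(which(spm@clusterId == id),
          name = sprintf("cluster-%d", rank),
          provenance = "derived-from-cluster")
}

#' Model-comparison ledger
#'
#' Runs several GLM specifications on one registered cohort and reports,
#' per specification: the best cluster's corrected p and extent and the
#' patch-level effect -- the synthetic twin of a model-exploration table.
#'
#' @param run a \code{\link{runPipeline}} bundle.
#' @param specs character vector of \code{\link{buildDesign}} specs.
#' @param outcome outcome assay to analyse.
#' @param nPerm permutations per specification.
#' @param patch quantification patch (default the frozen fixture).
#' @return data.frame with one row per specification.
#' @export
ledgerReport <- function(run, specs = c("exploration-height",
                                        "exploration-weight",
                                        "selected"),
                         outcome = "cmsd", nPerm = 500L,
                         patch = defaultNeckPatch()) {
    if (!length(specs))
        return(data.frame(model = character(), contrast = character(),
                          pCluster = numeric(), extent = integer(),
                          effectPerSD = numeric()))
    mesh <- run$model@template
    Y <- t(SummarizedExperiment::assay(run$se, outcome))
    sc <- scores(run$model, standardized = TRUE)
    graph <- meshGraph(mesh)
    rows <- lapply(specs, function(sp) {
        design <- buildDesign(run$cohort, sc, spec = sp,
                              nShapeModes = run$config$nShapeModes)
        ft <- effectPercentMap(fTest(fitGlm(design, Y, mesh = mesh)))
        ft <- correctedPMaps(ft, method = "permutation", nPerm = nPerm,
                             seed = run$config$seed, graph = graph)
        cl <- ft@clusters
        best <- if (nrow(cl)) cl[1, ] else
            data.frame(pCorrected = NA_real_, extent = NA_integer_)
        data.frame(model = sp,
                   contrast = colnames(design)[attr(design, "contrast")],
                   pCluster = best$pCorrected,
                   extent = best$extent,
                   effectPerSD = patchEffect(ft, patch))
    })
    do.call(rbind, rows)
}
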