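#' @include evaluate.R
NULL

#' Pipeline configuration
#'
#' Bundles all stage parameters with a master seed and output directory.
#' Any entry may be overridden; unset entries take the package defaults.
#' The configuration round-trips through YAML.
#'
#' @param outDir output directory.
#' @param seed master seed; stage seeds derive from it deterministically.
#' @param projection list of \code{\link{projectionConfig}} arguments.
#' @param thresholds list of \code{\link{maskThresholds}} arguments
#'   (\code{zT} in the z-normalized frame).
#' @param weights list of \code{\link{lossWeights}} arguments.
#' @param optimizer list of \code{\link{optimizerConfig}} arguments.
#' @param prepType preparation type to carve ("a"-"d").
#' @param generatorRank rank of the linear generator.
#' @param nTrain training-population size for the generator.
#' @param stopAfter run only up to this stage ("project", "mask",
#'   "reconstruct" or "evaluate").
#' @export
pipelineConfig <- function(outDir = "occlumap-out", seed = 1L,
                           projection = list(), thresholds = list(nzT = 0.3),
                           weights = list(), optimizer = list(nR = 200L,
                                                              nRestarts = 2L),
                           prepType = "a", generatorRank = 16L,
                           nTrain = 40L, stopAfter = "evaluate") {
    list(outDir = outDir, seed = as.integer(seed), projection = projection,
         thresholds = thresholds, weights = weights, optimizer = optimizer,
         prepType = prepType, generatorRank = as.integer(generatorRank),
         nTrain = as.integer(nTrain), stopAfter = stopAfter)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the
#'   \code{\link{pipelineConfig}} fields.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

writeProvenance <- function(path, stage, config, extra = list()) {
    jsonlite::write_json(c(list(stage = stage, seed = config$seed,
                                timestamp = "deterministic",
                                package = "occlumap"), extra),
                         paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
}

#' Run the full reconstruction pipeline on a synthetic tooth
#'
#' End-to-end demonstration pipeline: generate a synthetic population,
#' train the linear generator on its canonical depth maps, carve the
#' requested preparation into a held-out tooth, normalize and project it,
#' extract the preparation mask, reconstruct by latent inversion, merge,
#' back-project the merged map to a heightfield mesh, and evaluate
#' against the uncorrupted ground truth. Every artifact is written with
#' a JSON provenance sidecar; a manifest lists them all. Deterministic
#' for a fixed configuration.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML file).
#' @return invisibly, the manifest list (paths and headline numbers).
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    cfg <- do.call(projectionConfig, config$projection)
    seed <- config$seed
    manifest <- list(seed = seed)

    message("stage synth: generating population")
    pop <- generateToothDataset(config$nTrain + 1L, toothShapeParams(),
                                seed = seed)
    target <- pop[[1L]]
    trainMeshes <- pop[-1L]

    message("stage project: canonical depth maps")
    trainMaps <- lapply(seq_along(trainMeshes), function(i)
        projectTooth(trainMeshes[[i]], cfg, seed = seed + 10L * i))
    xTrueMap <- projectTooth(target, cfg, seed = seed + 1L)
    p <- file.path(config$outDir, "ground_truth.png")
    writeDepthMapPng(xTrueMap, p)
    writeProvenance(p, "project", config)
    manifest$groundTruth <- p
    if (identical(config$stopAfter, "project")) return(invisible(manifest))

    message("stage mask: carving and extracting the preparation")
    spec <- preparationSpec(config$prepType, target@metadata$params)
    carved <- carvePreparation(target, spec)
    zT <- spec$floorZ + (cfg@zNorm - max(carved$mesh@vertices[, 3L])) + 0.2
    th <- do.call(maskThresholds, utils::modifyList(list(zT = zT),
                                                   config$thresholds))
    mx <- extractPreparationMask(carved$mesh, cfg, th, seed = seed + 1L)
    p <- file.path(config$outDir, "preparation.png")
    writeDepthMapPng(mx$map, p); writeProvenance(p, "mask", config)
    pm <- file.path(config$outDir, "mask.png")
    writeMaskPng(mx$mask, pm); writeProvenance(pm, "mask", config)
    manifest$preparation <- p; manifest$mask <- pm
    if (identical(config$stopAfter, "mask")) return(invisible(manifest))

    message("stage fit-generator / reconstruct")
    G <- fitLinearGenerator(mirrorAugment(trainMaps),
                            rank = config$generatorRank)
    wts <- do.call(lossWeights, config$weights)
    opt <- do.call(optimizerConfig,
                   utils::modifyList(list(seed = seed), config$optimizer))
    xCor <- corrupt(mx$map@pixels, mx$mask)
    res <- optimizeLatent(xCor, mx$mask, mx$boundary, G, wts, opt)
    mergedMap <- new("DepthMap", pixels = res@xMerge, config = cfg,
                     provenance = "merged-reconstruction")
    p <- file.path(config$outDir, "merged.png")
    writeDepthMapPng(mergedMap, p); writeProvenance(p, "reconstruct", config,
        list(nDr = res@nDr, chosenRestart = res@chosenRestart,
             finalLoss = res@finalLosses[res@chosenRestart]))
    pc <- file.path(config$outDir, "clean.png")
    writeDepthMapPng(new("DepthMap", pixels = res@xClean, config = cfg,
                         provenance = "generated-clean"), pc)
    writeProvenance(pc, "reconstruct", config)
    tracePath <- file.path(config$outDir, "trace.csv")
    utils::write.csv(data.frame(step = seq_along(
        res@traces[[res@chosenRestart]]),
        loss = res@traces[[res@chosenRestart]]), tracePath,
        row.names = FALSE)
    manifest$merged <- p; manifest$clean <- pc; manifest$trace <- tracePath
    if (identical(config$stopAfter, "reconstruct")) return(invisible(manifest))

    message("stage evaluate: back-projection and metrics")
    mesh3d <- backproject(quantizeDepthMap(mergedMap))
    pmesh <- file.path(config$outDir, "merged_mesh.obj")
    writeMesh(mesh3d, pmesh); writeProvenance(pmesh, "evaluate", config)
    rmse <- rmseVsTruth(res@xMerge, xTrueMap@pixels, calibration(cfg))
    dd <- distanceDistribution(res@xMerge, xTrueMap@pixels, mx$mask,
                               calibration(cfg))
    summaryPath <- file.path(config$outDir, "summary.json")
    jsonlite::write_json(list(
        rmseMm = rmse, nDr = res@nDr,
        maskAreaFraction = relativeMaskArea(mx$mask, mx$map),
        cutoff95Mm = dd$cutoffMm,
        prepType = config$prepType, seed = seed),
        summaryPath, auto_unbox = TRUE, digits = NA)
    manifest$mergedMesh <- pmesh
    manifest$summary <- summaryPath
    manifest$rmseMm <- rmse
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    invisible(manifest)
}
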