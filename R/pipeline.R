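#' @include evaluate.R train.R synthetic.R preprocess.R
NULL

# md5 of an R object (via its serialization) for stage cache keys
.objChecksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.stageFresh <- function(stampPath, key, outputs) {
  file.exists(stampPath) && all(file.exists(outputs)) &&
    identical(readLines(stampPath, warn = FALSE)[1], key)
}

.stamp <- function(stampPath, key) writeLines(key, stampPath)

#' Pipeline configuration
#'
#' Bundles the per-stage configurations for a full run:
#' simulate -> crop -> train -> extract -> evaluate.
#'
#' @param outDir artifact directory.
#' @param seed master seed; every stage derives its streams from it.
#' @param spec a \linkS4class{SyntheticSpec} (its own seed is overridden by
#'   \code{seed}).
#' @param cropSize crop side in px (divisible by 8).
#' @param sourceWidths,targetWidths architecture widths.
#' @param epochs,learningRate,batchSize training settings.
#' @param layers layers to extract and sweep.
#' @param k kNN neighborhood size.
#' @param logLevel "info" or "quiet".
#' @return A config list; \code{\link{runPipeline}} consumes it. YAML files
#'   with these field names are accepted via \code{loadRunConfig}.
#' @export
runConfig <- function(outDir, seed = 1,
                      spec = syntheticSpec(),
                      cropSize = 32,
                      sourceWidths = c(16, 32, 32, 32, 32),
                      targetWidths = c(16, 32, 32),
                      epochs = 5, learningRate = 1e-4, batchSize = 64,
                      layers = paste0("Conv", 1:5), k = 11,
                      logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  spec@seed <- as.integer(seed)
  list(outDir = outDir, seed = as.integer(seed), spec = spec,
       cropSize = as.integer(cropSize),
       sourceWidths = as.integer(sourceWidths),
       targetWidths = as.integer(targetWidths),
       epochs = as.integer(epochs), learningRate = learningRate,
       batchSize = as.integer(batchSize), layers = layers, k = as.integer(k),
       logLevel = logLevel)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose fields mirror \code{\link{runConfig}}
#'   arguments; \code{spec} sub-fields mirror \code{\link{syntheticSpec}}.
#' @param overrides named list taking precedence over the file.
#' @export
loadRunConfig <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  specArgs <- y$spec
  y$spec <- if (is.null(specArgs)) syntheticSpec() else
    do.call(syntheticSpec, specArgs)
  do.call(runConfig, y)
}

#' Run the full pipeline
#'
#' Executes simulate -> crop -> train -> extract -> evaluate into
#' \code{outDir}. Each stage is skipped when its outputs exist and the
#' checksum of its configuration and inputs is unchanged. A resolved-config
#' snapshot and seed record are written alongside the artifacts.
#'
#' @param config from \code{\link{runConfig}} or \code{\link{loadRunConfig}}.
#' @return Invisibly, a list of artifact paths plus the layer-sweep report.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  info <- function(...) if (config$logLevel == "info")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  saveRDS(config, file.path(config$outDir, "resolved_config.rds"))
  writeLines(as.character(config$seed),
             file.path(config$outDir, "seed.txt"))

  # simulate ----------------------------------------------------------------
  dataDir <- file.path(config$outDir, "dataset")
  simKey <- .objChecksum(list("simulate", config$spec))
  simStamp <- file.path(config$outDir, "simulate.stamp")
  manifestPath <- file.path(dataDir, "manifest.tsv")
  if (!.stageFresh(simStamp, simKey, manifestPath)) {
    t0 <- Sys.time()
    generateDataset(config$spec, dataDir)
    .stamp(simStamp, simKey)
    info("simulate: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  } else info("simulate: cached")

  # crop --------------------------------------------------------------------
  storePath <- file.path(config$outDir, "crops.rds")
  ppc <- preprocessConfig(mode = "center_based", cropSize = config$cropSize,
                          minCellsPerImage = 2)
  cropKey <- .objChecksum(list("crop", simKey, ppc))
  cropStamp <- file.path(config$outDir, "crop.stamp")
  if (!.stageFresh(cropStamp, cropKey, storePath)) {
    t0 <- Sys.time()
    manifest <- readManifest(manifestPath)
    centers <- utils::read.delim(file.path(dataDir, "centers.tsv"))
    pp <- preprocessDataset(manifest, ppc, centers = centers)
    writeCropStore(pp$crops, storePath)
    .stamp(cropStamp, cropKey)
    info("crop: %d cells, %.1fs", nCells(pp$crops),
         as.numeric(Sys.time() - t0, units = "secs"))
  } else info("crop: cached")
  crops <- readCropStore(storePath)
  lay <- channelLayout(crops)
  mcfg <- modelConfig(cropSize = config$cropSize,
                      nStructural = length(structuralIndices(lay)),
                      nProtein = length(proteinIndices(lay)),
                      sourceWidths = config$sourceWidths,
                      targetWidths = config$targetWidths)

  # train -------------------------------------------------------------------
  weightsPath <- file.path(config$outDir, "weights.rds")
  tcfg <- trainConfig(epochs = config$epochs,
                      learningRate = config$learningRate,
                      batchSize = config$batchSize, seed = config$seed)
  trainKey <- .objChecksum(list("train", cropKey, mcfg, tcfg))
  trainStamp <- file.path(config$outDir, "train.stamp")
  if (!.stageFresh(trainStamp, trainKey, weightsPath)) {
    t0 <- Sys.time()
    fit <- trainModel(crops, mcfg, tcfg,
                      verbose = config$logLevel == "info")
    saveRDS(fit$model, weightsPath)
    utils::write.table(fit$history,
                       file.path(config$outDir, "loss_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stamp(trainStamp, trainKey)
    info("train: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  } else info("train: cached")
  model <- readRDS(weightsPath)

  # extract -----------------------------------------------------------------
  featPaths <- file.path(config$outDir,
                         sprintf("features_%s.tsv", config$layers))
  extKey <- .objChecksum(list("extract", trainKey, config$layers))
  extStamp <- file.path(config$outDir, "extract.stamp")
  if (!.stageFresh(extStamp, extKey, featPaths)) {
    t0 <- Sys.time()
    for (i in seq_along(config$layers))
      writeFeatureTable(extractFeatures(model, crops,
                                        layer = config$layers[i]),
                        featPaths[i])
    .stamp(extStamp, extKey)
    info("extract: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  } else info("extract: cached")

  # evaluate ----------------------------------------------------------------
  reportPath <- file.path(config$outDir, "layer_sweep.tsv")
  evalKey <- .objChecksum(list("evaluate", extKey, config$k))
  evalStamp <- file.path(config$outDir, "evaluate.stamp")
  labels <- utils::read.delim(file.path(dataDir, "labels.tsv"))
  labelMap <- stats::setNames(labels$class, labels$image_id)
  if (!.stageFresh(evalStamp, evalKey, reportPath)) {
    t0 <- Sys.time()
    sweep <- layerSweep(model, crops, labelMap, layers = config$layers,
                        k = config$k)
    utils::write.table(sweep, reportPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .stamp(evalStamp, evalKey)
    info("evaluate: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  } else info("evaluate: cached")
  report <- utils::read.delim(reportPath)
  invisible(list(dataDir = dataDir, storePath = storePath,
                 weightsPath = weightsPath, featurePaths = featPaths,
                 reportPath = reportPath, report = report))
}
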