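# Shared benchmark computations for the acceptance checks. Everything heavy
# (dataset, trainings, features) is computed once per test run and cached.

.benchCache <- new.env(parent = emptyenv())

benchSeed <- 1L
benchEpochs <- 8L

benchModelConfig <- function()
  modelConfig(cropSize = 32, nStructural = 1, nProtein = 1,
              sourceWidths = c(16, 32, 32, 32, 32))

benchDataset <- function() {
  if (is.null(.benchCache$ds)) {
    dir <- file.path(tempdir(), "ci-bench-ds")
    .benchCache$ds <- generateDataset(syntheticSpec(seed = benchSeed), dir)
  }
  .benchCache$ds
}

benchCrops <- function() {
  if (is.null(.benchCache$crops)) {
    ds <- benchDataset()
    pp <- preprocessDataset(ds$manifest,
                            preprocessConfig("center_based", cropSize = 32,
                                             minCellsPerImage = 2),
                            centers = ds$centers)
    .benchCache$crops <- pp$crops
  }
  .benchCache$crops
}

benchLabels <- function() {
  ds <- benchDataset()
  stats::setNames(ds$labels$class, ds$labels$image_id)
}

benchCellLabels <- function() {
  lab <- benchLabels()
  unname(lab[as.character(cropData(benchCrops())$image_id)])
}

benchFits <- function() {
  if (is.null(.benchCache$fits)) {
    .benchCache$fits <- lapply(benchSeed + 0:2, function(s)
      trainModel(benchCrops(), benchModelConfig(),
                 trainConfig(epochs = benchEpochs, seed = s)))
  }
  .benchCache$fits
}

benchAEFits <- function() {
  if (is.null(.benchCache$aefits)) {
    .benchCache$aefits <- lapply(benchSeed + 0:2, function(s)
      trainModel(benchCrops(), benchModelConfig(),
                 trainConfig(epochs = benchEpochs, seed = s,
                             mode = "autoencoder")))
  }
  .benchCache$aefits
}

benchBA <- function(model, layer) {
  key <- paste0("ba_", substr(digestModel(model), 1, 12), "_", layer)
  if (is.null(.benchCache[[key]])) {
    ft <- standardizeFeatures(extractFeatures(model, benchCrops(), layer))
    .benchCache[[key]] <- knnLooBalancedAccuracy(
      ft, benchCellLabels(), k = 11)$balancedAccuracy
  }
  .benchCache[[key]]
}

digestModel <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model@source[[1]]$W, f)
  unname(tools::md5sum(f))
}

# standardized Conv4 features of the first trained model, for the distance
# and multi-localization checks
benchFeatures <- function() {
  if (is.null(.benchCache$feat)) {
    ft <- extractFeatures(benchFits()[[1]]$model, benchCrops(), "Conv4")
    .benchCache$feat <- standardizeFeatures(ft)
  }
  .benchCache$feat
}
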