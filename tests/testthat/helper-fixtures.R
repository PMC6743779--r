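# Small in-code fixtures shared across test files.

# a tiny valid two-channel layout
tinyLayout <- function() ChannelLayout(c("marker", "protein"),
                                       structural = 1, protein = 2)

# a CellCropSet built directly in memory: nImages images x cellsPerImage
# cells of random [0,1] crops
tinyCropSet <- function(nImages = 2, cellsPerImage = 3, size = 16,
                        nChannels = 2, seed = 1) {
  set.seed(seed)
  n <- nImages * cellsPerImage
  px <- array(runif(size * size * nChannels * n), c(size, size, nChannels, n))
  cd <- S4Vectors::DataFrame(
    image_id = rep(sprintf("img%02d", seq_len(nImages)), each = cellsPerImage),
    cell_id = rep(sprintf("c%04d", seq_len(cellsPerImage)), nImages),
    field_index = 0L,
    center_row = 0, center_col = 0)
  layout <- if (nChannels == 2) tinyLayout() else
    ChannelLayout(c(paste0("s", seq_len(nChannels - 1)), "protein"),
                  structural = seq_len(nChannels - 1), protein = nChannels)
  new("CellCropSet", pixels = px, cellData = cd, layout = layout)
}

# a small synthetic dataset on disk, cached for the test run
tinyDataset <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "ci-tiny-ds")
    spec <- syntheticSpec(patternClasses = c("nuclear", "cytosolic"),
                          imagesPerClass = 2, cellsPerImage = c(4, 6),
                          seed = 7)
    cache <<- generateDataset(spec, dir)
    cache
  }
})

# reduced-profile model config for 32 px crops
tinyModelConfig <- function(nStructural = 1, nProtein = 1)
  modelConfig(cropSize = 32, nStructural = nStructural, nProtein = nProtein,
              sourceWidths = c(16, 32, 32, 32, 32))

# an even smaller config for speed in pure-shape tests
microModelConfig <- function()
  modelConfig(cropSize = 16, nStructural = 1, nProtein = 1,
              sourceWidths = c(4, 8, 8, 8, 8), targetWidths = c(4, 4, 8))
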