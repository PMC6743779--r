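test_that("ChannelLayout enforces disjoint covering channel roles", {
  lay <- ChannelLayout(c("rfp", "gfp"), structural = 1, protein = 2)
  expect_identical(structuralIndices(lay), 1L)
  expect_identical(proteinIndices(lay), 2L)
  expect_error(ChannelLayout(c("a", "b"), structural = 1:2, protein = 2),
               "disjoint")
  expect_error(ChannelLayout(c("a", "b", "c"), structural = 1, protein = 2),
               "cover")
  expect_error(ChannelLayout("a", structural = 1, protein = integer(0)),
               "non-empty")
  # name-based construction resolves to indices
  lay2 <- ChannelLayout(c("rfp", "gfp"), structural = "rfp", protein = "gfp")
  expect_identical(structuralIndices(lay2), 1L)
})

test_that("manifest round-trips and groups rows by image deterministically", {
  dir <- withr::local_tempdir()
  lay <- tinyLayout()
  f <- function(nm) {
    p <- file.path(dir, nm)
    tiff::writeTIFF(matrix(runif(64), 8, 8), p)
    nm
  }
  rows <- data.frame(
    image_id = c("b", "a", "b"), field_index = c(1L, 0L, 0L),
    path_marker = c(f("b1m.tif"), f("a0m.tif"), f("b0m.tif")),
    path_protein = c(f("b1p.tif"), f("a0p.tif"), f("b0p.tif")),
    label = "x")
  mpath <- file.path(dir, "manifest.tsv")
  writeManifest(new("DatasetManifest", rows = rows, layout = lay), mpath)
  m <- readManifest(mpath)
  expect_s4_class(m, "DatasetManifest")
  # grouping keeps first-appearance order of image ids, fields sorted within
  expect_identical(manifestRows(m)$image_id, c("b", "b", "a"))
  expect_identical(manifestRows(m)$field_index, c(0L, 1L, 0L))
  expect_identical(imageIds(m), c("b", "a"))
  # no loss, no duplication
  expect_identical(nrow(manifestRows(m)), 3L)
})

test_that("manifest errors name the missing column and the broken row", {
  dir <- withr::local_tempdir()
  lay <- tinyLayout()
  bad <- data.frame(field_index = 0L, path_marker = "x.tif",
                    path_protein = "y.tif")
  p <- file.path(dir, "bad.tsv")
  utils::write.table(bad, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readManifest(p, layout = lay), "image_id")
  bad2 <- data.frame(image_id = "i", field_index = 0L,
                     path_marker = "missing_file.tif",
                     path_protein = "missing_file2.tif")
  p2 <- file.path(dir, "bad2.tsv")
  utils::write.table(bad2, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readManifest(p2, layout = lay), "missing file")
})

test_that("six rows with three image ids group into three images", {
  dir <- withr::local_tempdir()
  lay <- tinyLayout()
  mk <- function(nm) {
    tiff::writeTIFF(matrix(runif(16), 4, 4), file.path(dir, nm))
    nm
  }
  rows <- data.frame(
    image_id = rep(c("i1", "i2", "i3"), each = 2),
    field_index = rep(0:1, 3),
    path_marker = vapply(sprintf("m%d.tif", 1:6), mk, character(1)),
    path_protein = vapply(sprintf("p%d.tif", 1:6), mk, character(1)))
  p <- file.path(dir, "m.tsv")
  utils::write.table(rows, p, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- readManifest(p, layout = lay)
  expect_length(imageIds(m), 3L)
})

test_that("crop store round-trips losslessly and preserves order", {
  crops <- tinyCropSet(nImages = 2, cellsPerImage = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  writeCropStore(crops, path)
  back <- readCropStore(path)
  expect_identical(cropArray(back), cropArray(crops))
  expect_identical(as.data.frame(cropData(back)),
                   as.data.frame(cropData(crops)))
  expect_identical(channelNames(channelLayout(back)),
                   channelNames(channelLayout(crops)))
})

test_that("crop store rejects mixed shapes and accepts the empty store", {
  path <- withr::local_tempfile(fileext = ".rds")
  good <- replicate(3, array(runif(32), c(4, 4, 2)), simplify = FALSE)
  bad <- c(good, list(array(runif(48), c(4, 4, 3))))
  expect_error(writeCropStore(bad, path, layout = tinyLayout()),
               "mixed shapes")
  writeCropStore(list(), path, layout = tinyLayout())
  empty <- readCropStore(path)
  expect_identical(nCells(empty), 0L)
})

test_that("feature tables round-trip within 1e-6 and reject NaN", {
  m <- matrix(rnorm(8), 2, 4)
  ft <- FeatureTable(m, imageId = c("i1", "i1"), cellId = c("a", "b"),
                     layer = "Conv2")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_equal(featureMatrix(back), featureMatrix(ft), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(featureLayer(back), "Conv2")
  expect_identical(cellKeys(back)$cell_id, c("a", "b"))
  # a 100 x 96 table yields 2 key columns + 96 feature columns
  big <- FeatureTable(matrix(0, 100, 96), imageId = rep("i", 100),
                      cellId = sprintf("c%03d", 1:100), layer = "Conv1")
  writeFeatureTable(big, path)
  header <- strsplit(readLines(path, n = 2)[2], "\t")[[1]]
  expect_length(header, 98L)
  # NaN violates the FeatureTable invariant at construction
  expect_error(FeatureTable(matrix(c(1, NaN), 2, 1), c("i", "i"),
                            c("a", "b"), "Conv1"))
})
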