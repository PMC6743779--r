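test_that("mixture parsing accepts pure classes and well-formed mixtures", {
  expect_identical(parsePatternClass("nuclear")$kind, "pure")
  pc <- parsePatternClass("mixture(nuclear,cytosolic,0.25)")
  expect_identical(pc$a, "nuclear")
  expect_equal(pc$alpha, 0.25)
  expect_error(parsePatternClass("golgi"), "unknown pattern class")
  expect_error(parsePatternClass("mixture(nuclear,golgi,0.5)"),
               "unknown pattern class")
})

test_that("mixture endpoint renders identically to the pure class", {
  spec <- syntheticSpec()
  set.seed(5)
  morph <- sampleMorphology(spec)
  set.seed(9)
  pure <- renderCell(morph, "nuclear")
  set.seed(9)
  mixed <- renderCell(morph, mixtureClass("nuclear", "cytosolic", 1))
  expect_identical(mixed$protein, pure$protein)
  expect_identical(mixed$structural, pure$structural)
})

test_that("nuclear rendering concentrates protein inside the nucleus", {
  spec <- syntheticSpec()
  set.seed(3)
  morph <- sampleMorphology(spec)
  cell <- renderCell(morph, "nuclear")
  p <- morph$patchSize
  ctr <- (p + 1) / 2
  r2 <- cellInpaint:::.ellipseR2(seq_len(p), seq_len(p),
                                 ctr + morph$nucOffsetRow,
                                 ctr + morph$nucOffsetCol,
                                 morph$nucleusFrac * morph$a,
                                 morph$nucleusFrac * morph$b, morph$theta)
  inside <- mean(cell$protein[r2 <= 1])
  outside <- mean(cell$protein[r2 > 1])
  expect_gt(inside, 5 * max(outside, 1e-9))
})

test_that("rendering is deterministic given the RNG state", {
  spec <- syntheticSpec()
  set.seed(11)
  m1 <- sampleMorphology(spec)
  c1 <- renderCell(m1, "punctate")
  set.seed(11)
  m2 <- sampleMorphology(spec)
  c2 <- renderCell(m2, "punctate")
  expect_identical(c1, c2)
})

test_that("generateImage places the requested cells and records centers", {
  spec <- syntheticSpec(cellsPerImage = c(12, 12), fieldSize = c(512, 512))
  set.seed(2)
  img <- generateImage("well1", "membrane", spec)
  ctr <- img@metadata$centers
  expect_identical(nrow(ctr), 12L)
  expect_true(all(ctr$row >= 0 & ctr$row < 512))
  d <- dim(img@fields[[1]])
  expect_identical(d, c(512L, 512L, 2L))
  expect_true(all(img@fields[[1]] >= 0))
  # single cell degenerate case
  spec1 <- syntheticSpec(cellsPerImage = c(1, 1))
  set.seed(2)
  img1 <- generateImage("w", "nuclear", spec1)
  expect_identical(nrow(img1@metadata$centers), 1L)
})

test_that("nuisance-off images render cells from the class template only", {
  spec <- syntheticSpec(cellsPerImage = c(3, 3), noiseSd = 0,
                        rampAmplitude = 0, cellJitterSd = 0,
                        gainRange = c(1, 1), psfSigma = 0,
                        diffuseFractionRange = c(0, 0),
                        radiusRange = c(13, 13),
                        eccentricityRange = c(1, 1),
                        nucleusFractionRange = c(0.45, 0.45))
  set.seed(4)
  img <- generateImage("w", "nuclear", spec)
  f <- img@fields[[1]]
  # with all nuisance off, per-cell protein content is identical up to
  # the (deterministic) geometry; total intensity per cell matches
  ctr <- img@metadata$centers
  sums <- vapply(seq_len(nrow(ctr)), function(k) {
    rr <- (ctr$row[k] - 15):(ctr$row[k] + 15) + 1
    cc <- (ctr$col[k] - 15):(ctr$col[k] + 15) + 1
    sum(f[rr, cc, 2])
  }, numeric(1))
  expect_lt(max(abs(sums - mean(sums))) / mean(sums), 0.05)
})

test_that("field too small for the requested cells raises a contract error", {
  spec <- syntheticSpec(cellsPerImage = c(40, 40), fieldSize = c(96, 96))
  set.seed(1)
  expect_error(generateImage("w", "nuclear", spec), "too small")
})

test_that("generateDataset is deterministic and writes a coherent manifest", {
  spec <- syntheticSpec(patternClasses = c("nuclear", "membrane"),
                        imagesPerClass = 2, cellsPerImage = c(3, 5),
                        seed = 31)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  r1 <- generateDataset(spec, d1)
  r2 <- generateDataset(spec, d2)
  expect_identical(length(imageIds(r1$manifest)), 4L)
  expect_identical(r1$labels, r2$labels)
  # byte-identical pixel data from the same seed
  sum1 <- unname(tools::md5sum(sort(list.files(d1, "\\.tif$",
                                               full.names = TRUE))))
  sum2 <- unname(tools::md5sum(sort(list.files(d2, "\\.tif$",
                                               full.names = TRUE))))
  expect_identical(sum1, sum2)
  # label table maps every image
  expect_setequal(r1$labels$image_id, imageIds(r1$manifest))
})

test_that("empty dataset specification yields a valid empty manifest", {
  spec <- syntheticSpec(imagesPerClass = 0)
  out <- generateDataset(spec, file.path(withr::local_tempdir(), "e"))
  expect_identical(nrow(manifestRows(out$manifest)), 0L)
  expect_identical(nrow(out$labels), 0L)
})

test_that("per-image mean intensity varies across images of one class", {
  ds <- tinyDataset()
  rows <- manifestRows(ds$manifest)
  lay <- channelLayout(ds$manifest)
  means <- vapply(which(rows$image_id %in%
                          ds$labels$image_id[ds$labels$class == "nuclear"]),
                  function(i) {
    f <- cellInpaint:::.readFieldArray(rows[i, ], lay)
    mean(f[, , 2])
  }, numeric(1))
  expect_gte(max(means) / min(means), 1.2)
})
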