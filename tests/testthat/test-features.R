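test_that("features are the spatial maxima of the named layer's maps", {
  cfg <- microModelConfig()
  model <- buildModel(cfg, seed = 2)
  crops <- tinyCropSet(nImages = 2, cellsPerImage = 3, size = 16)
  ft <- extractFeatures(model, crops, layer = "Conv1")
  m <- featureMatrix(ft)
  expect_identical(dim(m), c(6L, 4L))   # Conv1 width of the micro profile
  # cross-check one cell against a direct forward pass
  x <- cropArray(crops)[, , , 2, drop = FALSE]
  tap <- forwardSourceEncoder(model, x)$taps$Conv1
  expect_equal(m[2, ], apply(tap[, , , 1], 3, max), ignore_attr = TRUE)
  expect_error(extractFeatures(model, crops, layer = "Conv9"),
               "unknown layer")
})

test_that("feature extraction is permutation-equivariant over cells", {
  cfg <- microModelConfig()
  model <- buildModel(cfg, seed = 4)
  crops <- tinyCropSet(nImages = 2, cellsPerImage = 4, size = 16)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  f1 <- featureMatrix(extractFeatures(model, crops, "Conv2"))
  f2 <- featureMatrix(extractFeatures(model, crops[perm], "Conv2"))
  expect_equal(f2, f1[perm, ], ignore_attr = TRUE)
})

test_that("features of a flipped crop equal features under mirrored kernels", {
  # flipping the input is exactly equivalent to mirroring every convolution
  # kernel, so a model with flip-symmetric kernels has flip-invariant
  # max-pooled features; any conv/pool indexing defect breaks this identity
  cfg <- microModelConfig()
  model <- buildModel(cfg, seed = 6)
  for (i in seq_along(model@source)) {
    if (!is.null(model@source[[i]]$W)) {
      W <- model@source[[i]]$W
      model@source[[i]]$W <- (W + W[, 3:1, , , drop = FALSE]) / 2
    }
  }
  set.seed(8)
  px <- array(0, c(16, 16, 2, 1))
  px[5:12, 5:12, , 1] <- runif(128)
  cd <- S4Vectors::DataFrame(image_id = "i", cell_id = "a", field_index = 0L,
                             center_row = 0, center_col = 0)
  mk <- function(p) new("CellCropSet", pixels = p, cellData = cd,
                        layout = tinyLayout())
  f0 <- featureMatrix(extractFeatures(model, mk(px), "Conv2"))
  flipped <- px[, 16:1, , , drop = FALSE]
  f1 <- featureMatrix(extractFeatures(model, mk(flipped), "Conv2"))
  expect_equal(f0, f1, tolerance = 1e-10)
})

test_that("protein averaging takes unweighted means over grouped cells", {
  ft <- FeatureTable(rbind(c(0, 2), c(2, 0), c(4, 4)),
                     imageId = c("i1", "i1", "i2"),
                     cellId = c("a", "b", "c"), layer = "Conv3")
  grouping <- c(i1 = "P1", i2 = "P2")
  out <- averageProteinFeatures(ft, grouping)
  m <- featureMatrix(out)
  expect_identical(nrow(m), 2L)
  expect_equal(m["P1", ], c(1, 1), ignore_attr = TRUE)
  expect_equal(m["P2", ], c(4, 4), ignore_attr = TRUE)
  expect_error(averageProteinFeatures(ft, c(i1 = "P1")), "no protein group")
})

test_that("standardization hits zero mean / unit population sd with the stated degenerate rules", {
  m <- cbind(c(1, 3), c(5, 5))
  z <- standardizeFeatures(m)
  expect_equal(z[, 1], c(-1, 1))          # mean 2, population sd 1
  expect_equal(z[, 2], c(0, 0))           # constant column centered only
  z2 <- standardizeFeatures(z)
  expect_equal(z2, z, tolerance = 1e-12)  # idempotent
  expect_error(standardizeFeatures(m[1, , drop = FALSE]), ">= 2 rows")
  # FeatureTable path keeps the fitted scaler
  ft <- FeatureTable(m, c("i", "i"), c("a", "b"), "Conv1")
  sft <- standardizeFeatures(ft)
  expect_equal(S4Vectors::metadata(sft)$center, colMeans(m),
               ignore_attr = TRUE)
})
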