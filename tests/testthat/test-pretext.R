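test_that("the inpainting loss matches its definition on hand-set arrays", {
  yhat <- array(c(0, 1, 1, 0), c(2, 2, 1))
  y <- array(0, c(2, 2, 1))
  expect_equal(inpaintingLoss(yhat, y), 0.5)   # (1/4) * (0+1+1+0)
  expect_identical(inpaintingLoss(y, y), 0)
  expect_equal(inpaintingLoss(yhat, y), inpaintingLoss(y, yhat))
  expect_error(inpaintingLoss(array(0, c(2, 2, 1)), array(0, c(2, 3, 1))),
               "shape mismatch")
})

test_that("pair sampling covers every eligible cell once, never crossing images", {
  crops <- tinyCropSet(nImages = 4, cellsPerImage = 4)
  cd <- as.data.frame(cropData(crops))
  for (ep in 1:3) {
    pairs <- sampleEpochPairs(crops, seed = ep)
    expect_identical(nrow(pairs), nrow(cd))
    # each cell once as source
    expect_setequal(pairs$source_idx, seq_len(nrow(cd)))
    # no self pairs, no cross-image pairs
    expect_true(all(pairs$source_idx != pairs$target_idx))
    expect_identical(cd$image_id[pairs$source_idx],
                     cd$image_id[pairs$target_idx])
  }
  # determinism under the same seed
  expect_identical(sampleEpochPairs(crops, 5), sampleEpochPairs(crops, 5))
})

test_that("a two-cell image forces mutual pairing and singles are skipped", {
  cd <- data.frame(image_id = c("i", "i", "solo"),
                   cell_id = c("a", "b", "c"))
  expect_warning(pairs <- sampleEpochPairs(cd, 1), "single cell")
  expect_identical(nrow(pairs), 2L)
  expect_setequal(paste(pairs$source_id, pairs$target_id),
                  c("a b", "b a"))
  expect_error(suppressWarnings(
    sampleEpochPairs(data.frame(image_id = "x", cell_id = "a"), 1)),
    "no image has")
  expect_error(sampleEpochPairs(cd[0, ], 1), "empty crop store")
})

test_that("flip augmentation transforms a cell's channels jointly and involutes", {
  set.seed(1)
  pair <- list(xs = array(runif(32), c(4, 4, 2)),
               ys = array(runif(16), c(4, 4, 1)),
               xt = array(runif(32), c(4, 4, 2)),
               yt = array(runif(16), c(4, 4, 1)))
  none <- augmentPair(pair, c(FALSE, FALSE), c(FALSE, FALSE))
  expect_equal(none$xs, pair$xs, ignore_attr = TRUE)
  h <- augmentPair(pair, c(TRUE, FALSE), c(FALSE, FALSE))
  expect_equal(h$xs, pair$xs[, 4:1, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(h$ys, pair$ys[, 4:1, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(h$xt, pair$xt, ignore_attr = TRUE)   # target untouched
  twice <- augmentPair(augmentPair(pair, c(TRUE, TRUE), c(TRUE, FALSE)),
                       c(TRUE, TRUE), c(TRUE, FALSE))
  expect_equal(twice, lapply(pair, function(a) a), ignore_attr = TRUE)
})

test_that("loss is invariant to flipping prediction and target together", {
  set.seed(2)
  yhat <- array(runif(64), c(8, 8, 1))
  y <- array(runif(64), c(8, 8, 1))
  flip <- function(a) a[, 8:1, , drop = FALSE]
  expect_equal(inpaintingLoss(yhat, y), inpaintingLoss(flip(yhat), flip(y)))
})

test_that("the architecture produces the stated tap and output shapes", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 1)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  enc <- forwardSourceEncoder(model, x)
  expect_identical(dim(enc$taps$Conv1), c(32L, 32L, 16L, 3L))
  expect_identical(dim(enc$taps$Conv3), c(8L, 8L, 32L, 3L))
  expect_identical(dim(enc$taps$Conv5), c(8L, 8L, 32L, 3L))
  expect_identical(dim(enc$out), c(4L, 4L, 32L, 3L))
  # full forward emits a sigmoid-bounded protein prediction
  xt <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  fw <- cellInpaint:::.forwardFull(model, x, xt, training = FALSE)
  expect_identical(dim(fw$yhat), c(32L, 32L, 1L, 3L))
  expect_true(all(fw$yhat > 0 & fw$yhat < 1))
  # crop size not divisible by 8 is rejected
  expect_error(modelConfig(cropSize = 36), "divisible by 8")
  expect_error(modelConfig(sourceWidths = c(16, 32)), "length 5")
})

test_that("training runs, reports one loss per epoch, and is reproducible", {
  crops <- tinyCropSet(nImages = 2, cellsPerImage = 4, size = 16)
  cfg <- microModelConfig()
  tc <- trainConfig(epochs = 2, seed = 3, batchSize = 4)
  fit1 <- trainModel(crops, cfg, tc)
  expect_identical(nrow(fit1$history), 2L)
  expect_true(all(is.finite(fit1$history$loss)))
  fit2 <- trainModel(crops, cfg, tc)
  expect_identical(fit1$history, fit2$history)
  # autoencoder mode reconstructs its own input and trains the same encoder
  ta <- trainConfig(epochs = 1, seed = 3, batchSize = 4,
                    mode = "autoencoder")
  fa <- trainModel(crops, cfg, ta)
  expect_identical(fa$model@mode, "autoencoder")
  expect_identical(nrow(fa$history), 1L)
})

test_that("an overparameterized autoencoder drives reconstruction loss near zero", {
  # a constant dataset is memorizable: loss must collapse
  px <- array(rep(runif(16 * 16 * 2), 6), c(16, 16, 2, 6))
  cd <- S4Vectors::DataFrame(image_id = rep("i", 6),
                             cell_id = sprintf("c%d", 1:6),
                             field_index = 0L, center_row = 0, center_col = 0)
  crops <- new("CellCropSet", pixels = px, cellData = cd,
               layout = tinyLayout())
  fit <- trainModel(crops, microModelConfig(),
                    trainConfig(epochs = 600, seed = 1, batchSize = 6,
                                learningRate = 3e-3, augment = FALSE,
                                mode = "autoencoder"))
  expect_lt(tail(fit$history$loss, 1), 0.05 * fit$history$loss[1])
})
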