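test_that("Otsu center detection finds disc centroids and applies the area filter", {
  img <- matrix(0, 128, 128)
  mk <- function(cy, cx, r) {
    d2 <- outer((seq_len(128) - cy)^2, (seq_len(128) - cx)^2, "+")
    img[d2 <= r^2] <<- 0.9
  }
  mk(40, 40, 13)   # area ~531 px
  mk(90, 95, 13)
  det <- detectCentersOtsu(img, 400)
  expect_identical(nrow(det), 2L)
  # 0-based centroids within 1 px of the disc centers
  expect_lt(abs(det$row[1] - 39), 1)
  expect_lt(abs(det$col[1] - 39), 1)
  expect_lt(abs(det$row[2] - 89), 1)
  expect_lt(abs(det$col[2] - 94), 1)
  # deterministic order: row-major by first pixel
  expect_true(det$row[1] < det$row[2])

  # a disc below the area threshold yields no detections
  img2 <- matrix(0, 128, 128)
  d2 <- outer((seq_len(128) - 60)^2, (seq_len(128) - 60)^2, "+")
  img2[d2 <= 9.5^2] <- 0.9   # area ~283 px < 400
  expect_identical(nrow(detectCentersOtsu(img2, 400)), 0L)

  # degenerate constant channel: empty result with a warning
  expect_warning(res <- detectCentersOtsu(matrix(0, 32, 32), 400),
                 "constant")
  expect_identical(nrow(res), 0L)
})

test_that("crops are half-open windows with zero padding at field borders", {
  field <- array(seq_len(40 * 40 * 2) / (40 * 40 * 2), c(40, 40, 2))
  # interior: crop equals the central sub-array
  crop <- extractCrop(field, c(19.6, 20.2), 8)
  expect_identical(crop, field[17:24, 17:24, , drop = FALSE])
  # corner: three quarters of the crop is zero padding
  corner <- extractCrop(field, c(0, 0), 8)   # field values are all > 0
  expect_identical(sum(corner == 0), 2L * (64L - 16L))
  expect_identical(corner[5:8, 5:8, ], field[1:4, 1:4, , drop = FALSE])
  # out-of-bounds center is a contract error
  expect_error(extractCrop(field, c(40, 10), 8), "outside field")
  # constant field gives a constant crop
  const <- extractCrop(array(0.5, c(40, 40, 1)), c(20, 20), 8)
  expect_true(all(const == 0.5))
})

test_that("the mask-area filter applies the stated inclusive 5%/95% bounds", {
  expect_false(filterByArea(100, 64))        # below 0.05 * 4096 = 204.8
  expect_true(filterByArea(2048, 64))        # inside the band
  expect_false(filterByArea(0, 64))
  expect_false(filterByArea(4000, 64))       # above 0.95 * 4096 = 3891.2
  # boundaries are inclusive
  expect_true(filterByArea(0.05 * 64^2, 64))
  expect_true(filterByArea(0.95 * 64^2, 64))
})

test_that("normalization rescales channels to [0,1], zeroes constants, clips", {
  px <- array(0, c(4, 4, 2))
  px[, , 1] <- matrix(seq(10, 20, length.out = 16), 4, 4)
  px[, , 2] <- 7
  out <- normalizeCrop(px, "center_based")
  expect_equal(range(out[, , 1]), c(0, 1))
  expect_equal(out[, , 1], (px[, , 1] - 10) / 10, ignore_attr = TRUE)
  expect_true(all(out[, , 2] == 0))
  # human-style clip on structural channels after rescale
  px2 <- array(c(0, 0.02, 0.5, 1), c(2, 2, 1))
  out2 <- normalizeCrop(px2, "otsu_nucleus", clipThreshold = 0.05,
                        structuralIdx = 1)
  expect_identical(as.vector(out2), c(0, 0, 0.5, 1))
  expect_error(normalizeCrop(array(NA_real_, c(2, 2, 1)), "center_based"),
               "non-finite")
})

test_that("otsu-mode resize goes through bilinear interpolation to the crop size", {
  px <- array(runif(64 * 64), c(64, 64, 1))
  out <- normalizeCrop(px, "otsu_nucleus", targetSize = 16,
                       structuralIdx = integer(0))
  expect_identical(dim(out), c(16L, 16L, 1L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("preprocessDataset applies the min-cells filter and logs exclusions", {
  ds <- tinyDataset()
  cfg <- preprocessConfig("center_based", cropSize = 32,
                          minCellsPerImage = 2)
  pp <- preprocessDataset(ds$manifest, cfg, centers = ds$centers)
  expect_s4_class(pp$crops, "CellCropSet")
  expect_identical(nCells(pp$crops), nrow(ds$centers))
  expect_true(all(cropArray(pp$crops) >= 0 & cropArray(pp$crops) <= 1))
  # raising the threshold above any image's count drops every image
  cfg2 <- preprocessConfig("center_based", cropSize = 32,
                           minCellsPerImage = 50)
  pp2 <- preprocessDataset(ds$manifest, cfg2, centers = ds$centers)
  expect_identical(nCells(pp2$crops), 0L)
  expect_true(all(pp2$exclusions$unit == "image"))
  expect_match(pp2$exclusions$reason[1], "minimum")
  # center-based mode without centers is a contract error
  expect_error(preprocessDataset(ds$manifest, cfg), "requires precomputed")
})

test_that("cells are ordered by (field, row, col) with reproducible ids", {
  ds <- tinyDataset()
  cfg <- preprocessConfig("center_based", cropSize = 32,
                          minCellsPerImage = 2)
  pp1 <- preprocessDataset(ds$manifest, cfg, centers = ds$centers)
  pp2 <- preprocessDataset(ds$manifest, cfg,
                           centers = ds$centers[sample(nrow(ds$centers)), ])
  expect_identical(as.data.frame(cropData(pp1$crops)),
                   as.data.frame(cropData(pp2$crops)))
  expect_identical(cropArray(pp1$crops), cropArray(pp2$crops))
  cd <- as.data.frame(cropData(pp1$crops))
  for (im in unique(cd$image_id)) {
    sub <- cd[cd$image_id == im, ]
    expect_false(is.unsorted(order(sub$field_index, sub$center_row,
                                   sub$center_col)))
  }
})
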