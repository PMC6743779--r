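#' @include core-data.R
NULL

#' Preprocessing configuration
#'
#' Two cropping recipes are supported. \code{center_based} (yeast-style):
#' cell centers are supplied (e.g. by an external segmentation tool), a
#' \code{cropSize} window is cut around each center and min-max rescaled to
#' [0, 1]. \code{otsu_nucleus} (human-style): nuclei are detected by Otsu
#' thresholding the nuclear channel and labelling connected components,
#' objects under \code{minObjectAreaPx} are discarded, an
#' \code{intermediateCrop} window is cut around each center of mass, resized
#' bilinearly to \code{cropSize}, min-max rescaled, and structural-channel
#' values under \code{clipThreshold} are clipped to 0. Images with fewer than
#' \code{minCellsPerImage} surviving cells are dropped entirely.
#'
#' @param mode \code{"center_based"} or \code{"otsu_nucleus"}.
#' @param cropSize final crop side, px (even, >= 16; default 64).
#' @param intermediateCrop pre-resize crop side for otsu_nucleus mode.
#' @param minObjectAreaPx minimum nucleus component area (default 400 px).
#' @param areaFractionBounds inclusive (lower, upper) bounds on mask area as
#'   a fraction of the crop area, applied only when mask areas are supplied.
#' @param minCellsPerImage default 30 for center_based, 5 for otsu_nucleus.
#' @param clipThreshold structural-channel clip (otsu_nucleus mode).
#' @return A validated config list.
#' @export
preprocessConfig <- function(mode = c("center_based", "otsu_nucleus"),
                             cropSize = 64,
                             intermediateCrop = 512,
                             minObjectAreaPx = 400,
                             areaFractionBounds = c(0.05, 0.95),
                             minCellsPerImage = NULL,
                             clipThreshold = 0.05) {
  mode <- match.arg(mode)
  cropSize <- as.integer(cropSize)
  if (cropSize < 16L || cropSize %% 2L != 0L)
    stop("cropSize must be even and >= 16")
  b <- as.numeric(areaFractionBounds)
  if (!(b[1] >= 0 && b[1] < b[2] && b[2] <= 1))
    stop("areaFractionBounds must satisfy 0 <= lower < upper <= 1")
  if (is.null(minCellsPerImage))
    minCellsPerImage <- if (mode == "center_based") 30L else 5L
  list(mode = mode, cropSize = cropSize,
       intermediateCrop = as.integer(intermediateCrop),
       minObjectAreaPx = as.integer(minObjectAreaPx),
       areaFractionBounds = b,
       minCellsPerImage = as.integer(minCellsPerImage),
       clipThreshold = as.numeric(clipThreshold))
}

#' Detect nucleus centers by Otsu thresholding
#'
#' Binarizes the channel with an Otsu threshold, labels connected components,
#' drops components under the area threshold, and returns one center of mass
#' per remaining component. Component order is deterministic: row-major by
#' each component's first pixel.
#'
#' @param channel a 2-D numeric matrix.
#' @param minObjectAreaPx minimum component area in pixels.
#' @return A data.frame with 0-based \code{row}, \code{col} centroids and
#'   \code{area_px}; empty (with a warning) for a constant channel.
#' @export
detectCentersOtsu <- function(channel, minObjectAreaPx = 400) {
  stopifnot(is.matrix(channel))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0))
  rng <- range(channel)
  if (!all(is.finite(rng)))
    stop("contract error: channel contains non-finite values")
  if (rng[1] == rng[2]) {
    warning("constant channel: Otsu threshold undefined, no centers")
    return(empty)
  }
  scaled <- (channel - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled))
  mask <- scaled > thr
  lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  nlab <- max(lbl)
  if (nlab == 0) return(empty)
  labv <- as.vector(lbl)
  keepPix <- labv > 0
  labv <- labv[keepPix]
  rows0 <- as.vector(row(channel))[keepPix] - 1
  cols0 <- as.vector(col(channel))[keepPix] - 1
  area <- tabulate(labv, nbins = nlab)
  cy <- rowsum(rows0, labv)[, 1] / area
  cx <- rowsum(cols0, labv)[, 1] / area
  # row-major rank of each component's first pixel
  lin <- rows0 * ncol(channel) + cols0
  firstPix <- tapply(lin, labv, min)
  keep <- which(area >= minObjectAreaPx)
  keep <- keep[order(firstPix[keep])]
  data.frame(row = unname(cy[keep]), col = unname(cx[keep]),
             area_px = unname(area[keep]))
}

#' Extract a crop around a cell center
#'
#' The window is the half-open box \code{[r - H/2, r + H/2) x
#' [c - W/2, c + W/2)} in 0-based field coordinates (center rounded to the
#' nearest pixel); regions outside the field are zero-padded. All channels
#' are cropped identically.
#'
#' @param field an H0 x W0 x Z array (or an H0 x W0 matrix).
#' @param center numeric (row, col), 0-based; must lie inside the field.
#' @param cropSize crop side in px.
#' @return A cropSize x cropSize x Z array (not yet normalized).
#' @export
extractCrop <- function(field, center, cropSize) {
  if (is.matrix(field)) field <- array(field, dim = c(dim(field), 1L))
  d <- dim(field)
  r <- round(center[1])
  cl <- round(center[2])
  if (r < 0 || r >= d[1] || cl < 0 || cl >= d[2])
    stop("contract error: center (", center[1], ", ", center[2],
         ") outside field bounds")
  h <- cropSize %/% 2L
  out <- array(0, dim = c(cropSize, cropSize, d[3]))
  rr <- (r - h):(r + h - 1L)   # 0-based target rows
  cc <- (cl - h):(cl + h - 1L)
  okr <- rr >= 0 & rr < d[1]
  okc <- cc >= 0 & cc < d[2]
  out[which(okr), which(okc), ] <- field[rr[okr] + 1L, cc[okc] + 1L, ,
                                         drop = FALSE]
  out
}

#' Keep or reject a cell by segmentation-mask area
#'
#' @param maskAreaPx mask area of the centered object, in pixels.
#' @param cropSize crop side in px.
#' @param bounds inclusive (lower, upper) fractions of the crop area.
#' @return TRUE to keep, FALSE to reject.
#' @export
filterByArea <- function(maskAreaPx, cropSize, bounds = c(0.05, 0.95)) {
  stopifnot(maskAreaPx >= 0)
  lo <- bounds[1] * cropSize^2
  hi <- bounds[2] * cropSize^2
  maskAreaPx >= lo & maskAreaPx <= hi
}

#' Normalize a crop to [0, 1]
#'
#' Each channel is min-max rescaled to [0, 1] independently; constant
#' channels map to all zeros. In \code{otsu_nucleus} mode the crop is first
#' resized to \code{targetSize} by bilinear interpolation (after a Gaussian
#' antialiasing blur at sigma = downscale / 2), and after rescaling,
#' structural-channel values under \code{clipThreshold} are clipped to 0.
#'
#' @param pixels an H x W x Z array (or matrix).
#' @param mode \code{"center_based"} or \code{"otsu_nucleus"}.
#' @param clipThreshold clip level for structural channels (otsu mode).
#' @param structuralIdx indices of structural channels (otsu mode).
#' @param targetSize final side length for the otsu-mode resize, or NULL.
#' @return The normalized array, all values in [0, 1].
#' @export
normalizeCrop <- function(pixels, mode = c("center_based", "otsu_nucleus"),
                          clipThreshold = 0.05, structuralIdx = NULL,
                          targetSize = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!all(is.finite(pixels)))
    stop("contract error: non-finite pixel values")
  d <- dim(pixels)
  if (mode == "otsu_nucleus" && !is.null(targetSize) && targetSize != d[1]) {
    down <- d[1] / targetSize
    out <- array(0, dim = c(targetSize, targetSize, d[3]))
    for (z in seq_len(d[3])) {
      ch <- pixels[, , z]
      if (down > 1) ch <- EBImage::gblur(ch, sigma = down / 2)
      out[, , z] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(ch), w = targetSize, h = targetSize))
    }
    pixels <- out
    d <- dim(pixels)
  }
  for (z in seq_len(d[3])) {
    ch <- pixels[, , z]
    rng <- range(ch)
    pixels[, , z] <- if (rng[1] == rng[2]) 0 else
      (ch - rng[1]) / (rng[2] - rng[1])
  }
  if (mode == "otsu_nucleus" && length(structuralIdx)) {
    for (z in structuralIdx) {
      ch <- pixels[, , z]
      ch[ch < clipThreshold] <- 0
      pixels[, , z] <- ch
    }
  }
  pixels
}

# read one field of view (all channels) from manifest row
.readFieldArray <- function(row, layout) {
  chn <- channelNames(layout)
  mats <- lapply(chn, function(cn) {
    p <- row[[paste0("path_", cn)]]
    m <- if (grepl("\\.png$", p, ignore.case = TRUE))
      png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]   # tolerate stored RGB greyscale
    m
  })
  array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
}

#' Crop and normalize a full dataset
#'
#' Runs the configured recipe over every field of view of the manifest:
#' obtains centers (supplied in \code{center_based} mode; detected by
#' \code{\link{detectCentersOtsu}} on the first structural channel in
#' \code{otsu_nucleus} mode), extracts and normalizes crops, orders cells
#' within an image by (field_index, row, col), and drops images with fewer
#' than \code{minCellsPerImage} surviving cells.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param config from \code{\link{preprocessConfig}}.
#' @param centers data.frame(image_id, field_index, row, col) with 0-based
#'   coordinates; required in center_based mode. An optional \code{area_px}
#'   column enables the mask-area filter.
#' @return A list: \code{crops} (a \linkS4class{CellCropSet}),
#'   \code{cellCounts} (per-image surviving cells), and \code{exclusions}
#'   (log of every dropped cell/image with a reason).
#' @export
preprocessDataset <- function(manifest, config, centers = NULL) {
  stopifnot(is(manifest, "DatasetManifest"))
  layout <- channelLayout(manifest)
  rows <- manifestRows(manifest)
  if (config$mode == "center_based" && is.null(centers))
    stop("contract error: center_based mode requires precomputed centers")
  exclusions <- data.frame(image_id = character(), field_index = integer(),
                           unit = character(), reason = character())
  perImage <- list()
  for (imageId in unique(rows$image_id)) {
    irows <- rows[rows$image_id == imageId, , drop = FALSE]
    recs <- NULL
    pxList <- list()
    for (ri in seq_len(nrow(irows))) {
      fieldIdx <- irows$field_index[ri]
      field <- .readFieldArray(irows[ri, ], layout)
      ctr <- if (config$mode == "center_based") {
        centers[centers$image_id == imageId &
                  centers$field_index == fieldIdx, , drop = FALSE]
      } else {
        det <- detectCentersOtsu(field[, , structuralIndices(layout)[1]],
                                 config$minObjectAreaPx)
        if (nrow(det)) cbind(data.frame(image_id = imageId,
                                        field_index = fieldIdx), det)
        else det
      }
      if (!nrow(ctr)) next
      for (k in seq_len(nrow(ctr))) {
        if (!is.null(ctr$area_px) && config$mode == "center_based" &&
            !filterByArea(ctr$area_px[k], config$cropSize,
                          config$areaFractionBounds)) {
          exclusions <- rbind(exclusions, data.frame(
            image_id = imageId, field_index = fieldIdx, unit = "cell",
            reason = sprintf("mask area %d outside bounds", ctr$area_px[k])))
          next
        }
        rawSize <- if (config$mode == "otsu_nucleus")
          config$intermediateCrop else config$cropSize
        crop <- extractCrop(field, c(ctr$row[k], ctr$col[k]), rawSize)
        crop <- normalizeCrop(crop, mode = config$mode,
                              clipThreshold = config$clipThreshold,
                              structuralIdx = structuralIndices(layout),
                              targetSize = config$cropSize)
        pxList[[length(pxList) + 1L]] <- crop
        recs <- rbind(recs, data.frame(
          image_id = imageId, field_index = fieldIdx,
          center_row = ctr$row[k], center_col = ctr$col[k]))
      }
    }
    n <- length(pxList)
    if (n < config$minCellsPerImage) {
      exclusions <- rbind(exclusions, data.frame(
        image_id = imageId, field_index = NA_integer_, unit = "image",
        reason = sprintf("only %d cell(s), minimum is %d", n,
                         config$minCellsPerImage)))
      next
    }
    ord <- order(recs$field_index, recs$center_row, recs$center_col)
    recs <- recs[ord, , drop = FALSE]
    recs$cell_id <- sprintf("c%04d", seq_len(n))
    perImage[[imageId]] <- list(px = pxList[ord], recs = recs)
  }
  allRecs <- do.call(rbind, lapply(perImage, `[[`, "recs"))
  allPx <- unlist(lapply(perImage, `[[`, "px"), recursive = FALSE)
  if (is.null(allRecs)) {
    pixels <- array(numeric(0), dim = c(config$cropSize, config$cropSize,
                                        length(channelNames(layout)), 0L))
    cd <- DataFrame(image_id = character(), cell_id = character(),
                    field_index = integer(), center_row = numeric(),
                    center_col = numeric())
  } else {
    d1 <- dim(allPx[[1]])
    pixels <- array(unlist(allPx, use.names = FALSE),
                    dim = c(d1, length(allPx)))
    cd <- DataFrame(image_id = allRecs$image_id, cell_id = allRecs$cell_id,
                    field_index = as.integer(allRecs$field_index),
                    center_row = allRecs$center_row,
                    center_col = allRecs$center_col)
  }
  crops <- new("CellCropSet", pixels = pixels, cellData = cd, layout = layout)
  counts <- table(cd$image_id)
  list(crops = crops,
       cellCounts = data.frame(image_id = names(counts),
                               n_cells = as.integer(counts)),
       exclusions = exclusions)
}
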