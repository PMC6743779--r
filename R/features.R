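#' @include model.R
NULL

.validLayers <- paste0("Conv", 1:5)

#' Extract per-cell features from a named layer
#'
#' Runs the source cell encoder alone on each crop's full channels (no
#' target inputs are needed) and takes, for each filter of the named layer,
#' the maximum of the post-activation feature map over spatial positions.
#'
#' @param model an \linkS4class{InpaintingModel}.
#' @param crops a \linkS4class{CellCropSet} matching the model's crop size
#'   and channel counts.
#' @param layer one of \code{"Conv1"}..\code{"Conv5"}.
#' @param batchSize cells per forward pass.
#' @return A \linkS4class{FeatureTable} with one row per cell and one column
#'   per filter of the layer.
#' @export
extractFeatures <- function(model, crops, layer = "Conv3", batchSize = 256) {
  if (!layer %in% .validLayers)
    stop("contract error: unknown layer '", layer, "'")
  d <- dim(cropArray(crops))
  if (d[1] != model@config$cropSize)
    stop("crop size does not match the model configuration")
  n <- d[4]
  width <- model@config$sourceWidths[match(layer, .validLayers)]
  out <- matrix(0, n, width)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batchSize - 1L, n)
    x <- .batchInput(crops, idx, "full")
    taps <- forwardSourceEncoder(model, x, training = FALSE)$taps
    tp <- taps[[layer]]
    td <- dim(tp)
    m <- matrix(tp, td[1] * td[2], td[3] * td[4])
    mx <- apply(m, 2L, max)
    out[idx, ] <- t(matrix(mx, td[3], td[4]))
    i <- i + batchSize
  }
  cd <- cropData(crops)
  FeatureTable(out, imageId = cd$image_id, cellId = cd$cell_id, layer = layer)
}

#' Average single-cell features per protein
#'
#' @param table a \linkS4class{FeatureTable} of single cells.
#' @param grouping either a data.frame with \code{image_id} (optionally
#'   \code{cell_id}) and \code{protein} columns, or a character vector of
#'   proteins named by image_id. Every cell must be covered.
#' @return A \linkS4class{FeatureTable} with one row per protein (the
#'   unweighted mean over its cells); protein names serve as both keys.
#' @export
averageProteinFeatures <- function(table, grouping) {
  keys <- cellKeys(table)
  prot <- if (is.data.frame(grouping)) {
    if ("cell_id" %in% names(grouping)) {
      m <- match(paste(keys$image_id, keys$cell_id),
                 paste(grouping$image_id, grouping$cell_id))
      grouping$protein[m]
    } else grouping$protein[match(keys$image_id, grouping$image_id)]
  } else as.character(grouping[keys$image_id])
  if (anyNA(prot)) {
    miss <- unique(keys$image_id[is.na(prot)])
    stop("contract error: no protein group for cell(s) of image(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  m <- featureMatrix(table)
  sums <- rowsum(m, prot)
  counts <- as.vector(table(prot)[rownames(sums)])
  means <- sums / counts
  FeatureTable(means, imageId = rownames(sums), cellId = rownames(sums),
               layer = featureLayer(table))
}

#' Standardize features to zero mean and unit variance
#'
#' Each column is centered by its mean and scaled by its population standard
#' deviation; zero-variance columns are centered and left unscaled. The
#' fitted statistics are kept in \code{metadata()} so they can be applied to
#' held-out cells.
#'
#' @param table a \linkS4class{FeatureTable} (or plain matrix) with >= 2
#'   rows.
#' @param center,scale optional pre-fitted statistics to apply instead.
#' @return Standardized object of the same class; for FeatureTables the
#'   fitted \code{center}/\code{scale} sit in \code{metadata()}.
#' @export
standardizeFeatures <- function(table, center = NULL, scale = NULL) {
  m <- if (is(table, "FeatureTable")) featureMatrix(table) else
    as.matrix(table)
  if (nrow(m) < 2L && is.null(center))
    stop("contract error: need >= 2 rows to fit standardization")
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(sweep(m, 2L, center)^2))   # population sd
    scale[scale == 0] <- 1
  }
  z <- sweep(sweep(m, 2L, center), 2L, scale, "/")
  if (is(table, "FeatureTable")) {
    out <- FeatureTable(z, imageId = cellKeys(table)$image_id,
                        cellId = cellKeys(table)$cell_id,
                        layer = featureLayer(table))
    S4Vectors::metadata(out)$center <- center
    S4Vectors::metadata(out)$scale <- scale
    out
  } else z
}
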