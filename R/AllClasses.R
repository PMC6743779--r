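#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Channel roles of a multichannel image collection
#'
#' Splits the channel axis of an image collection into structural-marker
#' channels (present in every image of the collection, e.g. a cytosolic RFP or
#' a nucleus + microtubule stain pair) and protein channels (the tagged
#' biomolecule that varies image to image). The inpainting pretext task
#' predicts the protein channels of a target cell from its structural channels
#' plus a fully observed source cell.
#'
#' @slot channelNames ordered character vector naming all channels.
#' @slot structuralIndices integer indices of the structural-marker channels.
#' @slot proteinIndices integer indices of the protein channels.
#' @export
setClass("ChannelLayout", representation(
  channelNames = "character",
  structuralIndices = "integer",
  proteinIndices = "integer"
))

setValidity("ChannelLayout", function(object) {
  z1 <- object@structuralIndices
  z2 <- object@proteinIndices
  n <- length(object@channelNames)
  if (length(z1) == 0L) return("structural channel set must be non-empty")
  if (length(z2) == 0L) return("protein channel set must be non-empty")
  if (length(intersect(z1, z2)) > 0L)
    return("structural and protein channel sets must be disjoint")
  if (!setequal(union(z1, z2), seq_len(n)))
    return("structural and protein channel sets must cover all channels")
  TRUE
})

#' Construct a ChannelLayout
#'
#' @param channelNames character vector of channel names, in array order.
#' @param structural indices (or names) of the structural-marker channels.
#' @param protein indices (or names) of the protein channels.
#' @return A \linkS4class{ChannelLayout}.
#' @examples
#' ChannelLayout(c("rfp", "gfp"), structural = 1, protein = 2)
#' @export
ChannelLayout <- function(channelNames, structural, protein) {
  toIdx <- function(x) {
    if (is.character(x)) x <- match(x, channelNames)
    as.integer(x)
  }
  new("ChannelLayout", channelNames = as.character(channelNames),
      structuralIndices = toIdx(structural), proteinIndices = toIdx(protein))
}

#' A collection of fields of view from one experimental well
#'
#' One "image" is all fields of view of one experimental well; its cells are
#' assumed genetically identical and to share one protein-localization
#' pattern, the core assumption of the pretext task.
#'
#' @slot imageId well identifier.
#' @slot fields list of H0 x W0 x Z numeric arrays (non-negative, finite).
#' @slot layout the \linkS4class{ChannelLayout} shared by all fields.
#' @slot metadata free-form list (pattern class, ground-truth centers, ...).
#' @export
setClass("MicroscopyImage", representation(
  imageId = "character",
  fields = "list",
  layout = "ChannelLayout",
  metadata = "list"
))

setValidity("MicroscopyImage", function(object) {
  nz <- length(object@layout@channelNames)
  for (f in object@fields) {
    if (!is.array(f) || length(dim(f)) != 3L)
      return("each field of view must be an H x W x Z array")
    if (dim(f)[3] != nz)
      return("field channel count must match the channel layout")
    if (!all(is.finite(f)) || any(f < 0))
      return("pixel values must be finite and non-negative")
  }
  TRUE
})

#' Dataset manifest: files and grouping of fields of view into images
#'
#' @slot rows data.frame with columns image_id, field_index, one file-path
#'   column per channel (named \code{path_<channel>}), and optionally
#'   \code{label} (";"-separated localization terms) and \code{cell_line}.
#' @slot layout the \linkS4class{ChannelLayout} of the collection.
#' @export
setClass("DatasetManifest", representation(
  rows = "data.frame",
  layout = "ChannelLayout"
))

setValidity("DatasetManifest", function(object) {
  need <- c("image_id", "field_index",
            paste0("path_", object@layout@channelNames))
  miss <- setdiff(need, names(object@rows))
  if (length(miss))
    return(paste0("manifest lacks required column(s): ",
                  paste(miss, collapse = ", ")))
  TRUE
})

#' A set of normalized single-cell crops
#'
#' Crops are square H x W patches with all channels, pixel values in [0, 1]
#' after per-channel min-max normalization, keyed by (image_id, cell_id) with
#' the originating field and center recorded.
#'
#' @slot pixels numeric array H x W x Z x n_cells.
#' @slot cellData DataFrame with columns image_id, cell_id, field_index,
#'   center_row, center_col (0-based field coordinates).
#' @slot layout the \linkS4class{ChannelLayout}.
#' @export
setClass("CellCropSet", representation(
  pixels = "array",
  cellData = "DataFrame",
  layout = "ChannelLayout"
))

setValidity("CellCropSet", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 4L) return("pixels must be H x W x Z x n")
  if (d[1] != d[2]) return("crops must be square")
  if (d[3] != length(object@layout@channelNames))
    return("crop channel count must match the channel layout")
  if (nrow(object@cellData) != d[4])
    return("cellData rows must match the number of crops")
  need <- c("image_id", "cell_id", "field_index", "center_row", "center_col")
  if (!all(need %in% colnames(object@cellData)))
    return("cellData lacks required columns")
  if (d[4] > 0 && (!all(is.finite(object@pixels)) ||
                   min(object@pixels) < 0 || max(object@pixels) > 1))
    return("crop pixels must lie in [0, 1]")
  TRUE
})

#' Per-cell feature vectors from a named convolutional layer
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"features"}
#' (features in rows, cells in columns), colData keys \code{image_id} and
#' \code{cell_id}, and the tap layer name (\code{Conv1}..\code{Conv5}) in
#' \code{metadata()$layer}. Entries are the spatial maxima of the
#' post-activation feature maps of the source cell encoder.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("FeatureTable needs a 'features' assay")
  if (!all(c("image_id", "cell_id") %in% colnames(colData(object))))
    return("colData must carry image_id and cell_id")
  if (!all(is.finite(assay(object, "features"))))
    return("feature values must be finite")
  ly <- metadata(object)$layer
  if (is.null(ly) || !is.character(ly))
    return("metadata()$layer must name the tapped layer")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, cells in rows, features in columns.
#' @param imageId,cellId character vectors keying each cell.
#' @param layer name of the tapped convolutional layer.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(values, imageId, cellId, layer) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_f%03d", layer, seq_len(ncol(values)))
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    colData = DataFrame(image_id = as.character(imageId),
                        cell_id = as.character(cellId)))
  S4Vectors::metadata(se)$layer <- layer
  new("FeatureTable", se)
}

#' The paired cell inpainting network
#'
#' Holds the source cell encoder (an AlexNet-family stack of five 3x3
#' convolution + batch-norm + ReLU blocks with 2x2 max-pooling after blocks
#' 1, 2 and 5, exposing activation taps Conv1..Conv5), the small target
#' marker encoder (three blocks of 16/32/32 filters, pooled after each), and
#' the mirrored decoder (nearest-neighbour upsampling + convolution, sigmoid
#' head). In autoencoder mode the target encoder is unused and the decoder
#' reconstructs the input crop's own channels.
#'
#' @slot config list from \code{\link{modelConfig}}.
#' @slot source,target,decoder lists of layer parameter records.
#' @slot mode \code{"paired_inpainting"} or \code{"autoencoder"}.
#' @slot trained logical; whether any optimization has been applied.
#' @export
setClass("InpaintingModel", representation(
  config = "list",
  source = "list",
  target = "list",
  decoder = "list",
  mode = "character",
  trained = "logical"
))

#' Specification of a synthetic multichannel microscopy dataset
#'
#' Emulates the statistical structure of proteome-scale fluorescence screens:
#' many genetically identical cells per image sharing one protein-localization
#' pattern, structural channel(s) shared by the whole collection, a protein
#' channel varying image to image, per-cell morphology variation, and
#' per-image illumination nuisance (gain and planar gradient).
#'
#' @slot patternClasses character vector; each element a pure class name or
#'   \code{"mixture(classA,classB,alpha)"}.
#' @slot imagesPerClass,cellsPerImage,fieldSize,fieldsPerImage integers.
#' @slot radiusRange,eccentricityRange,nucleusFractionRange numeric ranges.
#' @slot gainRange,rampAmplitude,noiseSd,cellJitterSd,mixtureKappa nuisance.
#' @slot diffuseFractionRange per-cell unlocalized protein pool fraction.
#' @slot psfSigma Gaussian point-spread sigma in px; a (min, max) range is
#'   drawn per image (focus variation).
#' @slot backgroundRange per-image additive autofluorescence level range.
#' @slot structuralChannels 1 (single body+nucleus marker) or 2 (separate
#'   nucleus and body channels, HPA-style).
#' @slot seed integer; fully determines the dataset.
#' @export
setClass("SyntheticSpec", representation(
  patternClasses = "character",
  imagesPerClass = "integer",
  cellsPerImage = "integer",
  fieldSize = "integer",
  fieldsPerImage = "integer",
  radiusRange = "numeric",
  eccentricityRange = "numeric",
  nucleusFractionRange = "numeric",
  gainRange = "numeric",
  rampAmplitude = "numeric",
  noiseSd = "numeric",
  cellJitterSd = "numeric",
  diffuseFractionRange = "numeric",
  psfSigma = "numeric",
  backgroundRange = "numeric",
  mixtureKappa = "numeric",
  structuralChannels = "integer",
  seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  if (length(object@cellsPerImage) != 2L ||
      object@cellsPerImage[1] > object@cellsPerImage[2])
    return("cellsPerImage must be a (min, max) range")
  if (object@imagesPerClass < 0L) return("imagesPerClass must be >= 0")
  if (any(object@fieldSize < 32L)) return("fieldSize too small")
  if (diff(object@radiusRange) < 0) return("radiusRange must be a range")
  if (!object@structuralChannels %in% c(1L, 2L))
    return("structuralChannels must be 1 or 2")
  ok <- vapply(object@patternClasses,
               function(p) !inherits(try(parsePatternClass(p), silent = TRUE),
                                     "try-error"),
               logical(1))
  if (!all(ok))
    return(paste0("unknown pattern class: ",
                  paste(object@patternClasses[!ok], collapse = ", ")))
  TRUE
})
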