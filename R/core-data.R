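#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("channelNames", "ChannelLayout", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("structuralIndices", "ChannelLayout", function(x) x@structuralIndices)

#' @rdname accessors
#' @export
setMethod("proteinIndices", "ChannelLayout", function(x) x@proteinIndices)

#' @rdname accessors
#' @export
setMethod("channelLayout", "CellCropSet", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("channelLayout", "DatasetManifest", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("channelLayout", "MicroscopyImage", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("cropArray", "CellCropSet", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("cropData", "CellCropSet", function(x) x@cellData)

#' @rdname accessors
#' @export
setMethod("cropSize", "CellCropSet", function(x) dim(x@pixels)[1])

#' @rdname accessors
#' @export
setMethod("nCells", "CellCropSet", function(x) dim(x@pixels)[4])

#' @rdname accessors
#' @export
setMethod("manifestRows", "DatasetManifest", function(x) x@rows)

#' @rdname accessors
#' @export
setMethod("imageIds", "DatasetManifest",
          function(x) unique(as.character(x@rows$image_id)))

#' @rdname accessors
#' @export
setMethod("imageIds", "CellCropSet",
          function(x) unique(as.character(x@cellData$image_id)))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) t(assay(x, "features")))

#' @rdname accessors
#' @export
setMethod("featureLayer", "FeatureTable", function(x) metadata(x)$layer)

#' @rdname accessors
#' @export
setMethod("cellKeys", "FeatureTable", function(x)
  data.frame(image_id = colData(x)$image_id, cell_id = colData(x)$cell_id))

#' Subset a CellCropSet
#'
#' @param x a \linkS4class{CellCropSet}.
#' @param i integer or logical index over cells.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellCropSet", function(x, i, j, ..., drop = FALSE) {
  new("CellCropSet", pixels = x@pixels[, , , i, drop = FALSE],
      cellData = x@cellData[i, , drop = FALSE], layout = x@layout)
})

setMethod("show", "ChannelLayout", function(object) {
  cat("ChannelLayout:", length(object@channelNames), "channel(s)\n")
  cat("  structural:",
      paste(object@channelNames[object@structuralIndices], collapse = ", "), "\n")
  cat("  protein:   ",
      paste(object@channelNames[object@proteinIndices], collapse = ", "), "\n")
})

setMethod("show", "CellCropSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CellCropSet: %d crop(s) of %dx%d px, %d channel(s), %d image(s)\n",
              d[4], d[1], d[2], d[3],
              length(unique(object@cellData$image_id))))
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d field(s) of view in %d image(s), %d channel(s)\n",
              nrow(object@rows), length(imageIds(object)),
              length(object@layout@channelNames)))
})

setMethod("show", "InpaintingModel", function(object) {
  cfg <- object@config
  cat("InpaintingModel (", object@mode, if (object@trained) ", trained" else
      ", untrained", ")\n", sep = "")
  cat("  crop size:", cfg$cropSize, "px;",
      cfg$nStructural, "structural +", cfg$nProtein, "protein channel(s)\n")
  cat("  source encoder widths:", paste(cfg$sourceWidths, collapse = "/"), "\n")
})

## ---------------------------------------------------------------------------
## Manifest I/O

#' Read a dataset manifest
#'
#' The manifest is a UTF-8 TSV with a header row and required columns
#' \code{image_id}, \code{field_index}, plus one \code{path_<channel>} column
#' per channel; optional columns \code{label} (";"-separated localization
#' terms) and \code{cell_line}. The channel layout is read from a JSON
#' sidecar (\code{<path>.json}) unless given explicitly.
#'
#' @param path path to the manifest TSV.
#' @param layout a \linkS4class{ChannelLayout}, or NULL to read the sidecar.
#' @param checkFiles verify that every referenced image file exists.
#' @return A \linkS4class{DatasetManifest}; rows are grouped stably by
#'   image_id, then ordered by field_index.
#' @export
readManifest <- function(path, layout = NULL, checkFiles = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  rows <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (is.null(layout)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no channel layout given and no sidecar found at ", sidecar)
    layout <- readChannelLayout(sidecar)
  }
  need <- c("image_id", "field_index", paste0("path_", channelNames(layout)))
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("manifest format error: missing column(s) ",
         paste(miss, collapse = ", "))
  rows$image_id <- as.character(rows$image_id)
  rows$field_index <- as.integer(rows$field_index)
  # stable grouping: keep first-appearance order of image_id
  ord <- order(match(rows$image_id, unique(rows$image_id)), rows$field_index)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  # resolve relative paths against the manifest directory
  base <- dirname(normalizePath(path))
  for (cn in if (nrow(rows)) paste0("path_", channelNames(layout))
       else character(0)) {
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", rows[[cn]]), rows[[cn]],
                  file.path(base, rows[[cn]]))
    rows[[cn]] <- abs
    if (checkFiles) {
      bad <- which(!file.exists(abs))
      if (length(bad))
        stop("manifest I/O error: row ", bad[1], " references missing file ",
             abs[bad[1]])
    }
  }
  new("DatasetManifest", rows = rows, layout = layout)
}

#' Write a dataset manifest and its channel-layout sidecar
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param path output TSV path; the layout goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "DatasetManifest"))
  utils::write.table(manifest@rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeChannelLayout(manifest@layout, paste0(path, ".json"))
  invisible(path)
}

#' Read / write a ChannelLayout as JSON
#'
#' @param layout a \linkS4class{ChannelLayout}.
#' @param path a JSON file path.
#' @return \code{readChannelLayout} returns a \linkS4class{ChannelLayout}.
#' @export
writeChannelLayout <- function(layout, path) {
  jsonlite::write_json(list(channel_names = channelNames(layout),
                            structural = structuralIndices(layout),
                            protein = proteinIndices(layout)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeChannelLayout
#' @export
readChannelLayout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ChannelLayout(j$channel_names, structural = j$structural, protein = j$protein)
}

## ---------------------------------------------------------------------------
## Crop store

#' Persist and restore a set of single-cell crops
#'
#' The store is a single serialized container holding the full crop array,
#' cell keys, and the channel layout; round-trips are lossless and preserve
#' crop order.
#'
#' @param crops a \linkS4class{CellCropSet}, or a list of H x W x Z arrays
#'   (all of one shape) together with \code{cellData}.
#' @param path store file path.
#' @param cellData optional DataFrame/data.frame when \code{crops} is a list.
#' @param layout optional \linkS4class{ChannelLayout} when \code{crops} is a
#'   list.
#' @return \code{readCropStore} returns the \linkS4class{CellCropSet}.
#' @export
writeCropStore <- function(crops, path, cellData = NULL, layout = NULL) {
  if (is.list(crops) && !is(crops, "CellCropSet")) {
    if (length(crops)) {
      shapes <- vapply(crops, function(a) paste(dim(a), collapse = "x"),
                       character(1))
      if (length(unique(shapes)) > 1L)
        stop("contract error: crops have mixed shapes (",
             paste(unique(shapes), collapse = " vs "), ")")
      d <- dim(crops[[1]])
      px <- array(unlist(crops, use.names = FALSE), dim = c(d, length(crops)))
    } else {
      if (is.null(layout)) stop("empty crop list needs an explicit layout")
      px <- array(numeric(0),
                  dim = c(0L, 0L, length(channelNames(layout)), 0L))
    }
    if (is.null(cellData))
      cellData <- DataFrame(image_id = character(length(crops)),
                            cell_id = as.character(seq_along(crops)),
                            field_index = integer(length(crops)),
                            center_row = numeric(length(crops)),
                            center_col = numeric(length(crops)))
    crops <- new("CellCropSet", pixels = px, cellData = DataFrame(cellData),
                 layout = layout)
  }
  stopifnot(is(crops, "CellCropSet"))
  obj <- list(format = "cellInpaint-crop-store", version = 1L,
              pixels = crops@pixels,
              cellData = as.data.frame(crops@cellData),
              channel_names = channelNames(crops@layout),
              structural = structuralIndices(crops@layout),
              protein = proteinIndices(crops@layout),
              crop_size = dim(crops@pixels)[1])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeCropStore
#' @export
readCropStore <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cellInpaint-crop-store"))
    stop("not a crop store: ", path)
  new("CellCropSet", pixels = obj$pixels, cellData = DataFrame(obj$cellData),
      layout = ChannelLayout(obj$channel_names, obj$structural, obj$protein))
}

## ---------------------------------------------------------------------------
## Feature table I/O

#' Write / read a feature table as TSV
#'
#' Columns are \code{image_id}, \code{cell_id}, then one column per feature;
#' the tapped layer is recorded on a leading \code{# layer=} comment line.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param path TSV path.
#' @return \code{readFeatureTable} returns the \linkS4class{FeatureTable};
#'   numeric round-trip is exact to \code{1e-6} relative or better.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  m <- featureMatrix(table)
  if (!all(is.finite(m)))
    stop("contract error: feature table contains non-finite values")
  df <- cbind(cellKeys(table), as.data.frame(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# layer=", featureLayer(table)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  first <- readLines(path, n = 1L)
  layer <- if (startsWith(first, "# layer="))
    sub("^# layer=", "", first) else "unknown"
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("image_id", "cell_id")),
                    drop = FALSE])
  FeatureTable(m, imageId = df$image_id, cellId = df$cell_id, layer = layer)
}
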