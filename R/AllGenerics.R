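#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("structuralIndices", function(x) standardGeneric("structuralIndices"))

#' @rdname accessors
#' @export
setGeneric("proteinIndices", function(x) standardGeneric("proteinIndices"))

#' @rdname accessors
#' @export
setGeneric("channelLayout", function(x) standardGeneric("channelLayout"))

#' @rdname accessors
#' @export
setGeneric("cropArray", function(x) standardGeneric("cropArray"))

#' @rdname accessors
#' @export
setGeneric("cropData", function(x) standardGeneric("cropData"))

#' @rdname accessors
#' @export
setGeneric("cropSize", function(x) standardGeneric("cropSize"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureLayer", function(x) standardGeneric("featureLayer"))

#' @rdname accessors
#' @export
setGeneric("cellKeys", function(x) standardGeneric("cellKeys"))

#' @rdname accessors
#' @export
setGeneric("manifestRows", function(x) standardGeneric("manifestRows"))

#' @rdname accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
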