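#' @include nn-layers.R AllClasses.R
NULL

#' Configure the inpainting architecture
#'
#' The source cell encoder is an AlexNet-family stack: five 3x3 convolution
#' blocks (batch norm + ReLU) with 2x2 max-pooling after blocks 1, 2 and 5;
#' the default widths follow the canonical AlexNet family
#' (96/256/384/384/256). The target marker encoder has three blocks of
#' 16/32/32 filters with pooling after each, so for a crop of side S both
#' encoders bottom out at S/8 x S/8 and can be concatenated along the channel
#' axis. The decoder reverses the source widths with nearest-neighbour
#' upsampling + convolution and a sigmoid head. A reduced profile
#' (\code{sourceWidths = c(16, 32, 32, 32, 32)}) is the benchmark
#' configuration for CPU-scale runs.
#'
#' @param cropSize crop side in px; must be divisible by 8.
#' @param nStructural,nProtein channel counts |Z1|, |Z2|.
#' @param sourceWidths five filter counts for Conv1..Conv5.
#' @param targetWidths three filter counts for the target marker encoder.
#' @return A validated config list.
#' @export
modelConfig <- function(cropSize = 64, nStructural = 1, nProtein = 1,
                        sourceWidths = c(96, 256, 384, 384, 256),
                        targetWidths = c(16, 32, 32)) {
  if (length(sourceWidths) != 5L)
    stop("sourceWidths must have length 5 (Conv1..Conv5)")
  if (length(targetWidths) != 3L)
    stop("targetWidths must have length 3")
  cropSize <- as.integer(cropSize)
  if (cropSize %% 8L != 0L)
    stop("contract error: cropSize must be divisible by 8")
  list(cropSize = cropSize, nStructural = as.integer(nStructural),
       nProtein = as.integer(nProtein),
       sourceWidths = as.integer(sourceWidths),
       targetWidths = as.integer(targetWidths))
}

#' Build an (untrained) inpainting model
#'
#' @param config from \code{\link{modelConfig}}.
#' @param mode \code{"paired_inpainting"} (source encoder + target marker
#'   encoder + decoder predicting the target's protein channels) or
#'   \code{"autoencoder"} (source encoder + decoder reconstructing the input
#'   crop's own channels; target encoder unused).
#' @param seed optional integer seed for weight initialization.
#' @return An \linkS4class{InpaintingModel}.
#' @export
buildModel <- function(config, mode = c("paired_inpainting", "autoencoder"),
                       seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  sw <- config$sourceWidths
  tw <- config$targetWidths
  zin <- config$nStructural + config$nProtein
  poolAfter <- c(1L, 2L, 5L)
  source <- list()
  cin <- zin
  for (i in 1:5) {
    blk <- .blockLayer(cin, sw[i])
    blk$tap <- paste0("Conv", i)   # post-activation tap
    source <- c(source, list(blk))
    if (i %in% poolAfter) source <- c(source, list(list(type = "pool")))
    cin <- sw[i]
  }
  target <- list()
  cin <- config$nStructural
  for (i in 1:3) {
    target <- c(target, list(.blockLayer(cin, tw[i]), list(type = "pool")))
    cin <- tw[i]
  }
  dv <- rev(sw)
  din <- if (mode == "paired_inpainting") sw[5] + tw[3] else sw[5]
  outC <- if (mode == "paired_inpainting") config$nProtein else zin
  upBefore <- c(1L, 4L, 5L)   # mirrors the encoder's pool placement
  decoder <- list()
  cin <- din
  for (i in 1:5) {
    if (i %in% upBefore) decoder <- c(decoder, list(list(type = "upsample")))
    decoder <- c(decoder, list(.blockLayer(cin, dv[i])))
    cin <- dv[i]
  }
  decoder <- c(decoder, list(.convLayer(cin, outC, init = "head"),
                             list(type = "sigmoid")))
  new("InpaintingModel", config = config, source = source, target = target,
      decoder = decoder, mode = mode, trained = FALSE)
}

# stack crops into the network's channel order (structural first, protein
# last) for a set of cell indices
.batchInput <- function(crops, idx, channels = c("full", "structural",
                                                 "protein")) {
  channels <- match.arg(channels)
  lay <- channelLayout(crops)
  z <- switch(channels,
              full = c(structuralIndices(lay), proteinIndices(lay)),
              structural = structuralIndices(lay),
              protein = proteinIndices(lay))
  cropArray(crops)[, , z, idx, drop = FALSE]
}

#' Forward the source cell encoder with named activation taps
#'
#' @param model an \linkS4class{InpaintingModel}.
#' @param x an H x W x (|Z1|+|Z2|) x N batch (structural channels first).
#' @param training use batch statistics (TRUE) or running statistics.
#' @return A list with \code{out} (the bottleneck) and \code{taps}
#'   (post-activation Conv1..Conv5 maps).
#' @export
forwardSourceEncoder <- function(model, x, training = FALSE) {
  r <- .seqForward(model@source, x, training = training, keepCaches = FALSE)
  list(out = r$out, taps = r$taps)
}

#' Mean-squared inpainting loss
#'
#' For one pair, the sum of squared differences between the predicted and
#' actual target protein channels over all spatial positions (and protein
#' channels), divided by h * w. For batches (4-D arrays) the per-pair losses
#' are averaged.
#'
#' @param yhat,y numeric arrays of identical shape (h x w, h x w x C, or
#'   h x w x C x N).
#' @return A non-negative scalar; zero iff the arrays are equal.
#' @export
inpaintingLoss <- function(yhat, y) {
  if (!identical(dim(yhat), dim(y)) || is.null(dim(yhat)))
    stop("contract error: shape mismatch between prediction and target")
  d <- dim(yhat)
  n <- if (length(d) == 4L) d[4] else 1L
  sum((yhat - y)^2) / (d[1] * d[2]) / n
}

# full forward pass for a training batch; returns prediction + caches
.forwardFull <- function(model, xsFull, xt, training = TRUE) {
  s <- .seqForward(model@source, xsFull, training = training,
                   keepCaches = training)
  if (model@mode == "paired_inpainting") {
    t <- .seqForward(model@target, xt, training = training,
                     keepCaches = training)
    dcat <- .concatChannels(s$out, t$out)
  } else {
    t <- NULL
    dcat <- s$out
  }
  d <- .seqForward(model@decoder, dcat, training = training,
                   keepCaches = training)
  list(yhat = d$out, s = s, t = t, dec = d)
}

.concatChannels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
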