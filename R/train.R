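#' @include model.R
NULL

#' Sample one epoch of training pairs
#'
#' Every cell of every eligible image (>= 2 cells) appears exactly once as a
#' source; its target is drawn with uniform probability from the other cells
#' of the same image. The full pair list is then shuffled. Pairing never
#' crosses image boundaries and a cell is never paired with itself.
#'
#' @param cells a \linkS4class{CellCropSet} or a data.frame with
#'   \code{image_id} and \code{cell_id} columns.
#' @param seed integer; identical seeds give identical pairings.
#' @return A data.frame (image_id, source_id, target_id, source_idx,
#'   target_idx) where the *_idx columns index rows of \code{cells}.
#' @export
sampleEpochPairs <- function(cells, seed = 1) {
  cd <- if (is(cells, "CellCropSet")) as.data.frame(cropData(cells)) else
    as.data.frame(cells)
  if (nrow(cd) == 0L) stop("contract error: empty crop store")
  set.seed(as.integer(seed) %% 2147483647L)
  cd$.idx <- seq_len(nrow(cd))
  byImg <- split(cd, cd$image_id)
  singles <- names(byImg)[vapply(byImg, nrow, 1L) < 2L]
  if (length(singles))
    warning("image(s) with a single cell contribute no pairs: ",
            paste(singles, collapse = ", "))
  byImg <- byImg[vapply(byImg, nrow, 1L) >= 2L]
  if (length(byImg) == 0L)
    stop("contract error: no image has >= 2 cells")
  parts <- lapply(byImg, function(g) {
    n <- nrow(g)
    tgt <- integer(n)
    for (i in seq_len(n)) {
      cand <- setdiff(seq_len(n), i)
      tgt[i] <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L)]
    }
    data.frame(image_id = g$image_id, source_id = g$cell_id,
               target_id = g$cell_id[tgt], source_idx = g$.idx,
               target_idx = g$.idx[tgt], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, parts)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Augment a training pair by independent flips
#'
#' One flip draw applies jointly to the source cell's structural and protein
#' channels; an independent draw applies jointly to the target cell's marker
#' and protein channels, so the channels of one cell always transform
#' together.
#'
#' @param pair list with arrays \code{xs}, \code{ys}, \code{xt}, \code{yt}
#'   (H x W x C).
#' @param sourceFlips,targetFlips logical (horizontal, vertical); drawn from
#'   the RNG when NULL.
#' @return The augmented pair (same structure).
#' @export
augmentPair <- function(pair, sourceFlips = NULL, targetFlips = NULL) {
  if (is.null(sourceFlips)) sourceFlips <- stats::runif(2) < 0.5
  if (is.null(targetFlips)) targetFlips <- stats::runif(2) < 0.5
  fl <- function(a, f) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    if (f[2]) a <- a[dim(a)[1]:1, , , drop = FALSE]   # vertical: rows
    if (f[1]) a <- a[, dim(a)[2]:1, , drop = FALSE]   # horizontal: columns
    a
  }
  list(xs = fl(pair$xs, sourceFlips), ys = fl(pair$ys, sourceFlips),
       xt = fl(pair$xt, targetFlips), yt = fl(pair$yt, targetFlips))
}

#' Training configuration
#'
#' @param epochs passes over all cells as source (default 30).
#' @param learningRate Adam initial learning rate (default 1e-4).
#' @param batchSize pairs per optimization step.
#' @param seed master seed; pairing, augmentation and weight initialization
#'   draw from streams derived from it.
#' @param augment apply random horizontal/vertical flips.
#' @param mode \code{"paired_inpainting"} or \code{"autoencoder"}.
#' @return A validated config list.
#' @export
trainConfig <- function(epochs = 30, learningRate = 1e-4, batchSize = 64,
                        seed = 1, augment = TRUE,
                        mode = c("paired_inpainting", "autoencoder")) {
  mode <- match.arg(mode)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be > 0")
  list(epochs = epochs, learningRate = learningRate,
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       augment = isTRUE(augment), mode = mode)
}

#' Train a model by paired cell inpainting (or as an autoencoder)
#'
#' In \code{paired_inpainting} mode, minimizes the mean-squared inpainting
#' loss over sampled same-image pairs with independent flip augmentation. In
#' \code{autoencoder} mode the same source encoder + decoder reconstruct the
#' input crop's own channels and the target marker encoder is unused. One
#' epoch iterates over every eligible cell as source.
#'
#' @param crops a \linkS4class{CellCropSet}.
#' @param modelCfg from \code{\link{modelConfig}}; its crop size and channel
#'   counts must match the store.
#' @param trainCfg from \code{\link{trainConfig}}.
#' @param model optionally, an existing \linkS4class{InpaintingModel} to
#'   continue training (its mode must match \code{trainCfg$mode}).
#' @param verbose print per-epoch losses.
#' @return A list with the trained \code{model} and \code{history}
#'   (data.frame epoch, loss: mean per-pair loss of each epoch).
#' @export
trainModel <- function(crops, modelCfg, trainCfg, model = NULL,
                       verbose = FALSE) {
  stopifnot(is(crops, "CellCropSet"))
  d <- dim(cropArray(crops))
  if (d[1] != modelCfg$cropSize)
    stop("model cropSize (", modelCfg$cropSize,
         ") does not match the store (", d[1], ")")
  if (is.null(model))
    model <- buildModel(modelCfg, mode = trainCfg$mode,
                        seed = trainCfg$seed * 7L + 1L)
  if (model@mode != trainCfg$mode)
    stop("model mode does not match the training mode")
  paired <- trainCfg$mode == "paired_inpainting"
  state <- .adamInit(list(source = model@source, target = model@target,
                          decoder = model@decoder))
  hw <- d[1] * d[2]
  stepT <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (epoch in seq_len(trainCfg$epochs)) {
    pairs <- sampleEpochPairs(crops,
                              seed = (trainCfg$seed * 1009L + epoch) %%
                                2147483647L)
    set.seed((trainCfg$seed * 31L + epoch * 911L) %% 2147483647L)  # augment
    nb <- ceiling(nrow(pairs) / trainCfg$batchSize)
    epochLoss <- 0
    for (bi in seq_len(nb)) {
      sel <- ((bi - 1L) * trainCfg$batchSize + 1L):
        min(bi * trainCfg$batchSize, nrow(pairs))
      n <- length(sel)
      xsFull <- .batchInput(crops, pairs$source_idx[sel], "full")
      if (paired) {
        xt <- .batchInput(crops, pairs$target_idx[sel], "structural")
        yt <- .batchInput(crops, pairs$target_idx[sel], "protein")
      } else {
        xt <- NULL
        yt <- xsFull
      }
      if (trainCfg$augment) {
        sf <- matrix(stats::runif(2 * n) < 0.5, n, 2)   # source h, v
        tf <- matrix(stats::runif(2 * n) < 0.5, n, 2)
        xsFull <- .flipSamples(xsFull, sf[, 1], sf[, 2])
        if (paired) {
          xt <- .flipSamples(xt, tf[, 1], tf[, 2])
          yt <- .flipSamples(yt, tf[, 1], tf[, 2])
        } else {
          yt <- xsFull
        }
      }
      fw <- .forwardFull(model, xsFull, xt, training = TRUE)
      resid <- fw$yhat - yt
      loss <- sum(resid^2) / hw / n
      if (!is.finite(loss))
        stop("training diverged to a non-finite loss at epoch ", epoch)
      epochLoss <- epochLoss + loss * n
      dy <- 2 * resid / hw / n
      bd <- .seqBackward(fw$dec$layers, fw$dec$caches, dy)
      if (paired) {
        cs <- dim(fw$s$out)[3]
        ds <- bd$dx[, , seq_len(cs), , drop = FALSE]
        dt <- bd$dx[, , -seq_len(cs), , drop = FALSE]
        bt <- .seqBackward(fw$t$layers, fw$t$caches, dt)
      } else {
        ds <- bd$dx
        bt <- NULL
      }
      bs <- .seqBackward(fw$s$layers, fw$s$caches, ds)
      stepT <- stepT + 1L
      up <- .adamStep(fw$s$layers, bs$grads, state$source,
                      trainCfg$learningRate, stepT)
      model@source <- up$layers
      state$source <- up$state
      if (paired) {
        up <- .adamStep(fw$t$layers, bt$grads, state$target,
                        trainCfg$learningRate, stepT)
        model@target <- up$layers
        state$target <- up$state
      }
      up <- .adamStep(fw$dec$layers, bd$grads, state$decoder,
                      trainCfg$learningRate, stepT)
      model@decoder <- up$layers
      state$decoder <- up$state
    }
    meanLoss <- epochLoss / nrow(pairs)
    history <- rbind(history, data.frame(epoch = epoch, loss = meanLoss))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.6f", epoch, trainCfg$epochs,
                      meanLoss))
  }
  model@trained <- TRUE
  list(model = model, history = history)
}
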