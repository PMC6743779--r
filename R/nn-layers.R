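#' @useDynLib cellInpaint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Layer engine for the inpainting network.
##
## A network is an ordered list of layer records (plain lists with a $type).
## Batches are H x W x C x N arrays. Convolution / pooling / upsampling run
## in compiled code; batch normalization and activations are vectorized R.

# per-channel sums of an H x W x C x N array
.chSum <- function(x) {
  d <- dim(x)
  s <- .colSums(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(s, d[3], d[4]))
}

# broadcast a per-channel vector over H x W x C x N (recycles across N)
.chExpand <- function(v, d) rep(v, each = d[1] * d[2])

.convLayer <- function(cin, cout, init = c("he", "head")) {
  init <- match.arg(init)
  sd <- if (init == "he") sqrt(2 / (9 * cin)) else sqrt(1 / (9 * cin))
  list(type = "conv",
       W = array(stats::rnorm(9 * cin * cout, 0, sd), c(3, 3, cin, cout)),
       b = numeric(cout))
}

.bnLayer <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), eps = 1e-5, momentum = 0.1)
}

# fused convolution + batchnorm + ReLU block
.blockLayer <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(type = "block",
       W = array(stats::rnorm(9 * cin * cout, 0, sd), c(3, 3, cin, cout)),
       b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
       rm = numeric(cout), rv = rep(1, cout), eps = 1e-5, momentum = 0.1)
}

.layerForward <- function(layer, x, training) {
  switch(layer$type,
    block = {
      d <- dim(x)
      wd <- dim(layer$W)
      if (training) {
        r <- .cpp_block_fwd_train(x, layer$W, layer$b, layer$gamma,
                                  layer$beta, d, wd, layer$eps)
        M <- d[1] * d[2] * d[4]
        mom <- layer$momentum
        layer$rm <- (1 - mom) * layer$rm + mom * r$mu
        layer$rv <- (1 - mom) * layer$rv + mom * r$var * M / max(M - 1, 1)
        list(y = r$y, cache = list(x = x, y = r$y, xhat = r$xhat,
                                   invstd = r$invstd), layer = layer)
      } else {
        y <- .cpp_block_fwd_infer(x, layer$W, layer$b, layer$gamma,
                                  layer$beta, layer$rm, layer$rv, d, wd,
                                  layer$eps)
        list(y = y, cache = NULL, layer = layer)
      }
    },
    conv = {
      y <- .cpp_conv_fwd(x, layer$W, layer$b, dim(x), dim(layer$W))
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      M <- d[1] * d[2] * d[4]
      if (training) {
        r <- .cpp_bn_fwd_train(x, layer$gamma, layer$beta, d, layer$eps)
        mom <- layer$momentum
        layer$rm <- (1 - mom) * layer$rm + mom * r$mu
        layer$rv <- (1 - mom) * layer$rv + mom * r$var * M / max(M - 1, 1)
        list(y = r$y, cache = list(xhat = r$xhat, invstd = r$invstd),
             layer = layer)
      } else {
        y <- .cpp_bn_fwd_infer(x, layer$gamma, layer$beta, layer$rm,
                               layer$rv, d, layer$eps)
        list(y = y, cache = NULL, layer = layer)
      }
    },
    relu = {
      y <- .cpp_relu_fwd(x)
      list(y = y, cache = list(y = y), layer = layer)
    },
    pool = {
      r <- .cpp_maxpool_fwd(x, dim(x))
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)), layer = layer)
    },
    upsample = {
      y <- .cpp_upsample_fwd(x, dim(x))
      list(y = y, cache = list(ydim = dim(y)), layer = layer)
    },
    sigmoid = {
      y <- .cpp_sigmoid_fwd(x)
      list(y = y, cache = list(y = y), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

.layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    block = {
      r <- .cpp_block_bwd(dy, cache$y, cache$xhat, cache$invstd,
                          layer$gamma, cache$x, layer$W,
                          dim(cache$x), dim(layer$W))
      list(dx = r$dx, grads = list(W = r$dw, b = r$db, gamma = r$dgamma,
                                   beta = r$dbeta))
    },
    conv = {
      g <- .cpp_conv_bwd(cache$x, layer$W, dy, dim(cache$x), dim(layer$W))
      list(dx = g$dx, grads = list(W = g$dw, b = g$db))
    },
    bn = {
      r <- .cpp_bn_bwd(dy, cache$xhat, cache$invstd, layer$gamma, dim(dy))
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dx = .cpp_relu_bwd(dy, cache$y), grads = NULL),
    pool = list(dx = .cpp_maxpool_bwd(dy, cache$idx, cache$xdim),
                grads = NULL),
    upsample = list(dx = .cpp_upsample_bwd(dy, cache$ydim), grads = NULL),
    sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
    stop("unknown layer type: ", layer$type))
}

# forward a whole stack; returns output, per-layer caches (for backward),
# updated layers (bn running stats), and any tapped activations
.seqForward <- function(layers, x, training = FALSE, keepCaches = training) {
  caches <- vector("list", length(layers))
  taps <- list()
  for (i in seq_along(layers)) {
    r <- .layerForward(layers[[i]], x, training)
    x <- r$y
    layers[[i]] <- r$layer
    if (keepCaches) caches[[i]] <- r$cache
    if (!is.null(layers[[i]]$tap)) taps[[layers[[i]]$tap]] <- x
  }
  list(out = x, caches = caches, layers = layers, taps = taps)
}

.seqBackward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .layerBackward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

## Adam ----------------------------------------------------------------------

.adamInit <- function(layerGroups) {
  lapply(layerGroups, function(layers)
    lapply(layers, function(l) {
      ps <- intersect(names(l), c("W", "b", "gamma", "beta"))
      st <- lapply(ps, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
      names(st) <- ps
      st
    }))
}

.adamStep <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# flip helpers: apply horizontal (column) / vertical (row) flips to selected
# samples of an H x W x C x N array
.flipSamples <- function(x, hflip, vflip) {
  d <- dim(x)
  if (any(vflip)) x[, , , vflip] <- x[d[1]:1, , , vflip, drop = FALSE]
  if (any(hflip)) x[, , , hflip] <- x[, d[2]:1, , hflip, drop = FALSE]
  x
}
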