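## Minimal CNN engine: arrays are (H, W, C, N); convolution is im2col +
## BLAS matrix product; every layer has an explicit forward and backward.
## im2col gather indices are memoized per shape in a package-local cache.

.idx_cache <- new.env(parent = emptyenv())

## Linear gather indices for im2col over a padded (Hp, Wp, C) array,
## replicated across N samples. Rows ordered (kr, kc, ch); columns ordered
## output-position-fastest (ho, wo), then sample.
im2col_idx <- function(Hp, Wp, C, N, k, s) {
  key <- paste(Hp, Wp, C, N, k, s, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  starts <- as.vector(outer(as.integer((0:(Ho - 1)) * s + 1),
                            as.integer((0:(Wo - 1)) * s) * Hp, `+`))
  koff <- as.vector(outer(0:(k - 1), (0:(k - 1)) * Hp, `+`))
  offs <- as.vector(outer(koff, (0:(C - 1)) * (Hp * Wp), `+`))
  idx <- outer(as.integer(offs), as.integer(starts), `+`)
  idx <- outer(as.vector(idx), as.integer((0:(N - 1)) * (Hp * Wp * C)), `+`)
  dim(idx) <- c(k * k * C, Ho * Wo * N)
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

zero_pad <- function(x, p, fill = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

## ---- layer constructors ----------------------------------------------

layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L,
                       pad = (kernel - 1L) %/% 2L, bias = TRUE) {
  structure(list(type = "conv", in_ch = in_ch, out_ch = out_ch,
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad), bias = bias,
                 params = list(), opt = list()),
            class = "mps_layer")
}

layer_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  structure(list(type = "bn", ch = ch, momentum = momentum, eps = eps,
                 params = list(), opt = list(),
                 running_mean = rep(0, ch), running_var = rep(1, ch)),
            class = "mps_layer")
}

layer_relu <- function() {
  structure(list(type = "relu", params = list(), opt = list()), class = "mps_layer")
}

layer_maxpool <- function(kernel = 2L, stride = 2L, pad = 0L) {
  structure(list(type = "maxpool", kernel = as.integer(kernel),
                 stride = as.integer(stride), pad = as.integer(pad),
                 params = list(), opt = list()),
            class = "mps_layer")
}

layer_gap <- function() {
  structure(list(type = "gap", params = list(), opt = list()), class = "mps_layer")
}

layer_dense <- function(in_dim, out_dim) {
  structure(list(type = "dense", in_dim = in_dim, out_dim = out_dim,
                 params = list(), opt = list()),
            class = "mps_layer")
}

## Residual block: y = relu(branch(x) + shortcut(x)); shortcut is the
## identity unless the shape changes, then a 1x1 projection (+ BN).
layer_resblock <- function(branch, shortcut = NULL) {
  structure(list(type = "resblock", branch = branch, shortcut = shortcut,
                 params = list(), opt = list()),
            class = "mps_layer")
}

## ---- parameter initialization (He) -----------------------------------

init_layer <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$kernel^2 * layer$in_ch
    layer$params$W <- matrix(stats::rnorm(layer$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                             nrow = layer$out_ch)
    if (layer$bias) layer$params$b <- rep(0, layer$out_ch)
  } else if (layer$type == "bn") {
    layer$params$gamma <- rep(1, layer$ch)
    layer$params$beta <- rep(0, layer$ch)
  } else if (layer$type == "dense") {
    layer$params$W <- matrix(stats::rnorm(layer$out_dim * layer$in_dim,
                                          sd = sqrt(2 / layer$in_dim)),
                             nrow = layer$out_dim)
    layer$params$b <- rep(0, layer$out_dim)
  } else if (layer$type == "resblock") {
    layer$branch <- lapply(layer$branch, init_layer)
    if (!is.null(layer$shortcut)) layer$shortcut <- lapply(layer$shortcut, init_layer)
  }
  layer
}

## ---- forward ----------------------------------------------------------

conv_forward <- function(layer, x, keep) {
  d <- dim(x)
  xp <- zero_pad(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_idx(dp[1], dp[2], dp[3], dp[4], layer$kernel, layer$stride)
  xcol <- xp[as.vector(ii$idx)]                  # vector index: gather only
  dim(xcol) <- dim(ii$idx)
  y <- layer$params$W %*% xcol
  if (layer$bias) y <- y + layer$params$b
  out <- array(y, c(layer$out_ch, ii$Ho, ii$Wo, d[4]))
  out <- aperm(out, c(2, 3, 1, 4))
  cache <- if (keep) list(xcol = xcol, pdim = dp, xdim = d, ii = ii) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(layer, dout, cache) {
  d <- dim(dout)                                 # (Ho, Wo, Cout, N)
  dy <- aperm(dout, c(3, 1, 2, 4))
  dim(dy) <- c(layer$out_ch, d[1] * d[2] * d[4])
  dW <- dy %*% t(cache$xcol)
  grads <- list(W = dW)
  if (layer$bias) grads$b <- rowSums(dy)
  dxcol <- crossprod(layer$params$W, dy)
  dp <- cache$pdim
  dxp <- numeric(prod(dp))
  idx <- cache$ii$idx
  for (r in seq_len(nrow(idx))) {
    ## indices within one kernel-offset row are distinct: plain scatter-add
    dxp[idx[r, ]] <- dxp[idx[r, ]] + dxcol[r, ]
  }
  dim(dxp) <- dp
  p <- layer$pad
  dx <- if (p > 0) {
    dxp[p + seq_len(cache$xdim[1]), p + seq_len(cache$xdim[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, grads = grads)
}

bn_forward <- function(layer, x, train, keep) {
  d <- dim(x)
  C <- d[3]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  dim(ym) <- c(d[1], d[2], d[4], C)
  out <- aperm(ym, c(1, 2, 4, 3))
  cache <- if (keep) list(xhat = xhat, istd = istd, dims = d) else NULL
  list(out = out, cache = cache, layer = layer)
}

bn_backward <- function(layer, dout, cache) {
  d <- cache$dims
  C <- d[3]
  M <- d[1] * d[2] * d[4]
  dym <- aperm(dout, c(1, 2, 4, 3))
  dim(dym) <- c(M, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  ## standard batch-norm gradient with batch statistics
  t1 <- sweep(dym, 2, dbeta / M)
  t2 <- sweep(cache$xhat, 2, dgamma / M, `*`)
  dxm <- sweep(t1 - t2, 2, layer$params$gamma * cache$istd, `*`)
  dim(dxm) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dxm, c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_forward <- function(layer, x, keep) {
  d <- dim(x)
  ## fold channels into the sample axis and pool each plane
  x2 <- x
  dim(x2) <- c(d[1], d[2], 1L, d[3] * d[4])
  xp <- zero_pad(x2, layer$pad, fill = -Inf)
  dp <- dim(xp)
  ii <- im2col_idx(dp[1], dp[2], 1L, dp[4], layer$kernel, layer$stride)
  xcol <- xp[as.vector(ii$idx)]                  # vector index: gather only
  dim(xcol) <- dim(ii$idx)
  best <- xcol[1, ]
  arg <- rep(1L, length(best))
  for (r in 2:nrow(xcol)) {
    m <- xcol[r, ] > best
    best[m] <- xcol[r, m]
    arg[m] <- r
  }
  out <- array(best, c(ii$Ho, ii$Wo, d[3], d[4]))
  cache <- if (keep) list(arg = arg, ii = ii, pdim = dp, xdim = d) else NULL
  list(out = out, cache = cache)
}

pool_backward <- function(layer, dout, cache) {
  dxp <- numeric(prod(cache$pdim))
  dv <- as.vector(dout)
  idx <- cache$ii$idx
  for (r in seq_len(nrow(idx))) {
    sel <- cache$arg == r
    if (any(sel)) dxp[idx[r, sel]] <- dxp[idx[r, sel]] + dv[sel]
  }
  dim(dxp) <- cache$pdim
  p <- layer$pad
  d <- cache$xdim
  dx <- if (p > 0) {
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

gap_forward <- function(x, keep) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(xm), nrow = d[3])       # (C, N)
  list(out = out, cache = if (keep) list(dims = d) else NULL)
}

gap_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(rep(as.vector(dout), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  list(dx = dx, grads = NULL)
}

layer_forward <- function(layer, x, train, keep) {
  switch(layer$type,
    conv = c(conv_forward(layer, x, keep), list(layer = layer)),
    bn = bn_forward(layer, x, train, keep),
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = if (keep) list(mask = x > 0) else NULL, layer = layer)
    },
    maxpool = c(pool_forward(layer, x, keep), list(layer = layer)),
    gap = c(gap_forward(x, keep), list(layer = layer)),
    dense = {
      y <- layer$params$W %*% x + layer$params$b
      list(out = y, cache = if (keep) list(x = x) else NULL, layer = layer)
    },
    resblock = {
      br <- chain_forward(layer$branch, x, train, keep)
      sc <- if (is.null(layer$shortcut)) list(out = x, caches = NULL, layers = NULL) else {
        chain_forward(layer$shortcut, x, train, keep)
      }
      s <- br$out + sc$out
      out <- pmax(s, 0)
      layer$branch <- br$layers
      if (!is.null(layer$shortcut)) layer$shortcut <- sc$layers
      cache <- if (keep) list(branch = br$caches, shortcut = sc$caches, mask = s > 0) else NULL
      list(out = out, cache = cache, layer = layer)
    },
    stopf("unknown layer type '%s'", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = conv_backward(layer, dout, cache),
    bn = bn_backward(layer, dout, cache),
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = pool_backward(layer, dout, cache),
    gap = gap_backward(dout, cache),
    dense = list(dx = crossprod(layer$params$W, dout),
                 grads = list(W = dout %*% t(cache$x), b = rowSums(dout))),
    resblock = {
      ds <- dout * cache$mask
      br <- chain_backward(layer$branch, ds, cache$branch)
      if (is.null(layer$shortcut)) {
        dx <- br$dx + ds
        sc_grads <- NULL
      } else {
        sc <- chain_backward(layer$shortcut, ds, cache$shortcut)
        dx <- br$dx + sc$dx
        sc_grads <- sc$grads
      }
      list(dx = dx, grads = list(branch = br$grads, shortcut = sc_grads))
    },
    stopf("unknown layer type '%s'", layer$type))
}

## Forward through a list of layers; returns updated layers (BN running
## stats) and, when keep, one cache per layer.
chain_forward <- function(layers, x, train, keep) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train, keep)
    x <- r$out
    layers[[i]] <- r$layer
    if (keep) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, layers = layers)
}

chain_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- r$dx
    grads[i] <- list(r$grads)                    # keep NULL slots in place
  }
  list(dx = dout, grads = grads)
}

## ---- losses and updates ----------------------------------------------

softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

## Mean cross-entropy over the batch; labels are 0-based class indices.
cross_entropy <- function(logits, labels) {
  n <- ncol(logits)
  probs <- softmax_probs(logits)
  ii <- cbind(as.integer(labels) + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[ii], 1e-12)))
  dlogits <- probs
  dlogits[ii] <- dlogits[ii] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

## SGD with momentum and decoupled weight decay on W matrices only.
sgd_step_layer <- function(layer, grads, lr, momentum, weight_decay) {
  if (layer$type == "resblock") {
    for (i in seq_along(layer$branch)) {
      layer$branch[[i]] <- sgd_step_layer(layer$branch[[i]], grads$branch[[i]],
                                          lr, momentum, weight_decay)
    }
    if (!is.null(layer$shortcut)) {
      for (i in seq_along(layer$shortcut)) {
        layer$shortcut[[i]] <- sgd_step_layer(layer$shortcut[[i]], grads$shortcut[[i]],
                                              lr, momentum, weight_decay)
      }
    }
    return(layer)
  }
  if (is.null(grads)) return(layer)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm == "W" && weight_decay > 0) g <- g + weight_decay * layer$params[[nm]]
    v <- layer$opt[[nm]]
    if (is.null(v)) v <- g * 0
    v <- momentum * v - lr * g
    layer$opt[[nm]] <- v
    layer$params[[nm]] <- layer$params[[nm]] + v
  }
  layer
}

count_layer_params <- function(layer) {
  n <- sum(vapply(layer$params, length, integer(1)))
  if (layer$type == "resblock") {
    n <- n + sum(vapply(layer$branch, count_layer_params, numeric(1)))
    if (!is.null(layer$shortcut)) {
      n <- n + sum(vapply(layer$shortcut, count_layer_params, numeric(1)))
    }
  }
  n
}
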