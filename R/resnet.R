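#' Residual network architecture specification
#'
#' Describes a five-stage residual classifier for 50x200 single-channel
#' suture images: stage 0 is one convolution plus one max-pooling layer;
#' stages 1-4 hold residual blocks (3, 4, 6 and 3 bottleneck blocks in the
#' default 50-layer layout); a global average pooling layer and a fully
#' connected layer with softmax over the five age ranges close the network.
#' Each residual block learns `F(x) = H(x) - x` and adds it back over an
#' identity shortcut (`y = x + F(x, W)`, output `relu(y)`); when the block
#' changes resolution or width the shortcut is a 1x1 projection
#' convolution.
#'
#' `resnet50_spec()` is the canonical layout; `resnet_small_spec()` is a
#' compact basic-block variant suitable for CPU-scale experiments on
#' synthetic data.
#'
#' @param blocks integer vector, residual blocks per stage.
#' @param widths integer vector, base width per stage (bottleneck blocks
#'   expand to `4 * width` output channels).
#' @param block `"bottleneck"` (1x1-3x3-1x1) or `"basic"` (3x3-3x3).
#' @param stem_channels,stem_kernel,stem_stride stage-0 convolution.
#' @param stem_pool,stem_pool_stride,stem_pool_pad stage-0 max pooling.
#' @param stage_strides stride of each stage's first block.
#' @param input_shape `c(H, W, channels)`; suture images are
#'   `c(50, 200, 1)`.
#' @param classes number of output classes.
#' @param use_bn include batch normalization after every convolution.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(blocks = c(3, 4, 6, 3), widths = c(64, 128, 256, 512),
                         block = c("bottleneck", "basic"),
                         stem_channels = 64, stem_kernel = 7, stem_stride = 2,
                         stem_pool = 3, stem_pool_stride = 2, stem_pool_pad = 1,
                         stage_strides = c(1, 2, 2, 2),
                         input_shape = c(50, 200, 1), classes = 5,
                         use_bn = TRUE) {
  block <- match.arg(block)
  if (length(blocks) != length(widths) || length(blocks) != length(stage_strides)) {
    stopf("blocks, widths and stage_strides must have equal length")
  }
  structure(list(blocks = as.integer(blocks), widths = as.integer(widths),
                 block = block, stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 stem_pool = as.integer(stem_pool),
                 stem_pool_stride = as.integer(stem_pool_stride),
                 stem_pool_pad = as.integer(stem_pool_pad),
                 stage_strides = as.integer(stage_strides),
                 input_shape = as.integer(input_shape),
                 classes = as.integer(classes), use_bn = isTRUE(use_bn)),
            class = "network_spec")
}

#' @rdname network_spec
#' @export
resnet50_spec <- function(input_shape = c(50, 200, 1), classes = 5) {
  network_spec(input_shape = input_shape, classes = classes)
}

#' @rdname network_spec
#' @export
resnet_small_spec <- function(input_shape = c(50, 200, 1), classes = 5) {
  network_spec(blocks = c(1, 1), widths = c(16, 32), block = "basic",
               stem_channels = 8, stem_kernel = 5, stem_stride = 2,
               stem_pool = 2, stem_pool_stride = 2, stem_pool_pad = 0,
               stage_strides = c(2, 2), input_shape = input_shape,
               classes = classes)
}

conv_bn <- function(in_ch, out_ch, kernel, stride, use_bn, pad = (kernel - 1L) %/% 2L) {
  if (use_bn) {
    list(layer_conv(in_ch, out_ch, kernel, stride, pad, bias = FALSE),
         layer_bn(out_ch))
  } else {
    list(layer_conv(in_ch, out_ch, kernel, stride, pad, bias = TRUE))
  }
}

make_block <- function(in_ch, width, stride, type, use_bn) {
  out_ch <- if (type == "bottleneck") 4L * width else width
  branch <- if (type == "bottleneck") {
    c(conv_bn(in_ch, width, 1L, stride, use_bn), list(layer_relu()),
      conv_bn(width, width, 3L, 1L, use_bn), list(layer_relu()),
      conv_bn(width, out_ch, 1L, 1L, use_bn))
  } else {
    c(conv_bn(in_ch, width, 3L, stride, use_bn), list(layer_relu()),
      conv_bn(width, width, 3L, 1L, use_bn))
  }
  shortcut <- if (stride != 1L || in_ch != out_ch) {
    conv_bn(in_ch, out_ch, 1L, stride, use_bn, pad = 0L)
  } else NULL
  layer_resblock(branch, shortcut)
}

#' Build a residual classifier network
#'
#' Instantiates the architecture described by a [network_spec()]: every
#' convolution computes `f(X (x) W + b)` with ReLU activation (batch
#' normalization between convolution and activation when enabled), and
#' every residual block adds its learned residual onto the identity
#' shortcut, so with all residual branches at zero the network reduces to
#' an identity chain over the stage-0 features. Parameters use He
#' initialization, deterministic given the seed.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed for parameter initialization.
#' @return an object of class `mps_network`.
#' @export
build_network <- function(spec = resnet50_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  layers <- c(
    conv_bn(spec$input_shape[3], spec$stem_channels, spec$stem_kernel,
            spec$stem_stride, spec$use_bn),
    list(layer_relu(),
         layer_maxpool(spec$stem_pool, spec$stem_pool_stride, spec$stem_pool_pad))
  )
  in_ch <- spec$stem_channels
  for (st in seq_along(spec$blocks)) {
    for (b in seq_len(spec$blocks[st])) {
      stride <- if (b == 1L) spec$stage_strides[st] else 1L
      layers <- c(layers, list(make_block(in_ch, spec$widths[st], stride,
                                          spec$block, spec$use_bn)))
      in_ch <- if (spec$block == "bottleneck") 4L * spec$widths[st] else spec$widths[st]
    }
  }
  layers <- c(layers, list(layer_gap(), layer_dense(in_ch, spec$classes)))
  layers <- with_seed(seed, lapply(layers, init_layer))
  structure(list(layers = layers, spec = spec, seed = as.integer(seed)),
            class = "mps_network")
}

#' @export
print.mps_network <- function(x, ...) {
  cat(sprintf("<mps_network> %s, stages [%s] x widths [%s], %s classes, %s parameters\n",
              x$spec$block, paste(x$spec$blocks, collapse = ","),
              paste(x$spec$widths, collapse = ","), x$spec$classes,
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param net an `mps_network`.
#' @return integer-valued count.
#' @export
param_count <- function(net) {
  sum(vapply(net$layers, count_layer_params, numeric(1)))
}

## Coerce images to the network input tensor: (H, W, C, N), scaled from
## 8-bit gray to [-1, 1].
as_input_tensor <- function(x, input_shape) {
  d <- dim(x)
  if (is.matrix(x)) {
    x <- array(x, c(d[1], d[2], 1, 1))
  } else if (length(d) == 3) {
    x <- array(x, c(d[1], d[2], 1, d[3]))
  }
  d <- dim(x)
  if (d[1] != input_shape[1] || d[2] != input_shape[2] || d[3] != input_shape[3]) {
    stopf("input shape %dx%dx%d does not match the network input %dx%dx%d",
          d[1], d[2], d[3], input_shape[1], input_shape[2], input_shape[3])
  }
  (x - 127.5) / 127.5
}

## Forward pass over the whole network. Returns logits (classes x N), the
## (possibly BN-updated) network, and per-layer caches when keep = TRUE.
net_forward <- function(net, x, train = FALSE, keep = train) {
  r <- chain_forward(net$layers, x, train, keep)
  net$layers <- r$layers
  list(logits = r$out, net = net, caches = r$caches)
}

#' Class probabilities for a batch of suture images
#'
#' @param net an `mps_network`.
#' @param images a 50x200 matrix, or an array `c(H, W, N)` of 8-bit images.
#' @return a list with `probs` (N x classes matrix, rows summing to 1) and
#'   `labels` (0-based argmax labels, ties broken towards the lowest
#'   label).
#' @export
net_predict <- function(net, images) {
  x <- as_input_tensor(images, net$spec$input_shape)
  logits <- net_forward(net, x, train = FALSE, keep = FALSE)$logits
  probs <- t(softmax_probs(logits))
  colnames(probs) <- as.character(seq_len(net$spec$classes) - 1L)
  labels <- max.col(probs, ties.method = "first") - 1L
  list(probs = probs, labels = labels)
}
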