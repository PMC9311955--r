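#' Grad-CAM heat map for one suture image
#'
#' Explains a class score of the residual classifier by gradient-weighted
#' class activation mapping. With `A^k` the k-th channel of the last
#' convolutional feature layer (the input of the global average pooling
#' layer) and `y^c` the pre-softmax score of class `c`, the channel weights
#' are the spatial means of the back-propagated gradient,
#' `alpha_k = (1/Z) * sum_ij d y^c / d A^k_ij` with `Z` the number of
#' feature positions, and the map is `L = ReLU(sum_k alpha_k A^k)` --
#' non-negative by construction. The map is bilinearly upsampled to the
#' 50x200 image frame and min-max normalized to `[0, 1]` for overlay (an
#' all-zero map stays zero).
#'
#' @param model a fitted `suture_cnn` or an `mps_network`.
#' @param img a 50x200 8-bit image.
#' @param class 0-based target class; default is the predicted class.
#' @return an object of class `gradcam_heatmap`: `alpha` (channel
#'   weights), `map` (feature-resolution non-negative map), `overlay_map`
#'   (50x200, in `[0, 1]`), `class`, `score` (the class logit) and `probs`.
#' @export
gradcam_map <- function(model, img, class = NULL) {
  net <- if (inherits(model, "suture_cnn")) model$net else model
  stopifnot(inherits(net, "mps_network"))
  x <- as_input_tensor(img, net$spec$input_shape)
  if (dim(x)[4] != 1) stopf("gradcam_map explains one image at a time")
  types <- vapply(net$layers, function(l) l$type, character(1))
  g <- which(types == "gap")
  if (length(g) != 1) stopf("network has no global average pooling layer")
  ## features A: forward up to the layer before GAP (eval mode)
  lower <- chain_forward(net$layers[seq_len(g - 1L)], x, train = FALSE, keep = FALSE)
  A <- lower$out                                  # (H', W', K, 1)
  head_layers <- net$layers[g:length(net$layers)]
  up <- chain_forward(head_layers, A, train = FALSE, keep = TRUE)
  logits <- up$out
  probs <- softmax_probs(logits)
  if (is.null(class)) class <- which.max(logits[, 1]) - 1L
  class <- as.integer(class)
  if (class < 0 || class >= net$spec$classes) {
    stopf("class %d outside 0..%d", class, net$spec$classes - 1L)
  }
  ## d y^c / d A by backprop of the unit gradient through the head only
  dlogits <- matrix(0, nrow = nrow(logits), ncol = 1)
  dlogits[class + 1L, 1] <- 1
  dA <- chain_backward(head_layers, dlogits, up$caches)$dx
  d <- dim(A)
  alpha <- apply(dA[, , , 1, drop = FALSE], 3, mean)           # spatial mean per channel
  L <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) L <- L + alpha[k] * A[, , k, 1]
  L <- pmax(L, 0)
  ov <- resize_bilinear(L, net$spec$input_shape[1], net$spec$input_shape[2])
  ov <- pmax(ov, 0)
  if (max(ov) > 0) ov <- ov / max(ov)
  structure(list(alpha = alpha, map = L, overlay_map = ov, class = class,
                 score = logits[class + 1L, 1], probs = as.vector(probs)),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("<gradcam_heatmap> class %d (logit %.3f), %dx%d feature map, %d channels\n",
              x$class, x$score, nrow(x$map), ncol(x$map), length(x$alpha)))
  invisible(x)
}

#' Overlay a Grad-CAM heat map on the fused suture image
#'
#' Alpha-blends a red-intensity colormap onto the grayscale image: the
#' redder a region, the stronger the model's dependence on it. The blend
#' weight at each pixel is `alpha * heat`, so a zero map returns the pure
#' grayscale image and a uniform map a uniform tint.
#'
#' @param heat a `gradcam_heatmap` (or a 50x200 matrix in `[0, 1]`).
#' @param img the matching [fused_image()] or 50x200 8-bit matrix.
#' @param alpha maximum blend weight in `[0, 1]`.
#' @return an RGB array `c(50, 200, 3)` with values in `[0, 1]`.
#' @export
overlay <- function(heat, img, alpha = 0.4) {
  h <- if (inherits(heat, "gradcam_heatmap")) heat$overlay_map else heat
  g <- if (inherits(img, "fused_image")) img$pixels else img
  if (!identical(dim(h), dim(g))) {
    stopf("heat map (%s) and image (%s) shapes differ",
          paste(dim(h), collapse = "x"), paste(dim(g), collapse = "x"))
  }
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  gray <- g / 255
  w <- alpha * h
  out <- array(0, dim = c(dim(g), 3))
  out[, , 1] <- gray * (1 - w) + w                # red channel towards 1
  out[, , 2] <- gray * (1 - w)
  out[, , 3] <- gray * (1 - w)
  out
}

#' Fraction of heat mass inside the suture band
#'
#' Measures localization of a heat map: the share of total (upsampled)
#' heat that falls inside the band region -- either a set of 1-based row
#' indices of the 50x200 frame, or a logical mask such as the per-phantom
#' construction truth from [suture_band_mask()].
#'
#' @param heat a `gradcam_heatmap` (or a plain heat matrix).
#' @param band integer vector of row indices, or a 50x200 logical mask.
#' @return a number in `[0, 1]` (`NA` if the map is all zero).
#' @export
heat_band_fraction <- function(heat, band) {
  m <- if (inherits(heat, "gradcam_heatmap")) heat$overlay_map else heat
  tot <- sum(m)
  if (tot == 0) return(NA_real_)
  if (is.logical(band)) {
    if (!identical(dim(band), dim(m))) stopf("mask and heat map shapes differ")
    sum(m[band]) / tot
  } else {
    sum(m[band, ]) / tot
  }
}
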