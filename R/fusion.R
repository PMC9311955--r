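#' Fusion parameters
#'
#' Controls the pairwise merge fusion and the sharpening step.
#'
#' `d_mode` sets the adjustment factor `d` in the fusion formula, a damping
#' term based on the maximum gray-scale difference of the two images being
#' fused: `"max"` (default) uses `d = max_ij |img1_ij - img2_ij|`, so larger
#' inter-slice disagreement gives gentler enhancement; `"fixed"` uses the
#' constant `d_fixed`.
#'
#' `grouping` selects how the enhancement fraction is read: `"damped"`
#' (default) evaluates `A * (1 + (A - e) / (255 + d))`, which keeps the mean
#' gray level a fixed point for any `d`; `"additive"` evaluates
#' `A * (1 + (A - e) / 255 + d)`, provided for comparison.
#'
#' @param d_mode `"max"` or `"fixed"`.
#' @param d_fixed value of `d` when `d_mode = "fixed"`.
#' @param grouping `"damped"` or `"additive"`.
#' @param sharpen_strength non-negative sharpening weight `k`; `0` disables
#'   sharpening.
#' @param clip clip fused values to `[0, 255]` (default `TRUE`).
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(d_mode = c("max", "fixed"), d_fixed = 0,
                          grouping = c("damped", "additive"),
                          sharpen_strength = 0.5, clip = TRUE) {
  d_mode <- match.arg(d_mode)
  grouping <- match.arg(grouping)
  if (sharpen_strength < 0) stopf("sharpen_strength must be >= 0")
  if (d_mode == "fixed" && d_fixed < 0) stopf("d_fixed must be >= 0")
  structure(list(d_mode = d_mode, d_fixed = d_fixed, grouping = grouping,
                 sharpen_strength = sharpen_strength, clip = clip),
            class = "fusion_params")
}

fuse_pair_raw <- function(img1, img2, params) {
  A <- (img1 + img2) / 2
  e <- mean(A)
  d <- if (params$d_mode == "max") max(abs(img1 - img2)) else params$d_fixed
  P <- if (params$grouping == "damped") {
    A * (1 + (A - e) / (255 + d))
  } else {
    A * (1 + (A - e) / 255 + d)
  }
  if (params$clip) P <- clip255(P)
  P
}

#' Fuse two suture ROI images
#'
#' Pixel-level weighted fusion with contrast enhancement. With
#' `A_ij = (img1_ij + img2_ij) / 2` the average gray value at each point,
#' `e = mean(A)` the total average gray level, and `d` the adjustment factor
#' (see [fusion_params()]), the fused value is
#' `P_ij = A_ij * (1 + (A_ij - e) / (255 + d))`: pixels brighter than the
#' average are pushed up and darker pixels pushed down, so shared structure
#' is enhanced rather than washed out. The operation is symmetric in its two
#' inputs. Values are clipped to `[0, 255]` and, when `quantize = TRUE`,
#' rounded half-up to 8 bits.
#'
#' @param img1,img2 equal-shaped numeric matrices in `[0, 255]`.
#' @param params a [fusion_params()] object.
#' @param quantize round the result to 8-bit (default `TRUE`). Internal
#'   rounds of [fuse_stack()] keep floating point and quantize only once at
#'   the end.
#' @return a matrix of the common shape.
#' @export
fuse_pair <- function(img1, img2, params = fusion_params(), quantize = TRUE) {
  if (!identical(dim(img1), dim(img2))) {
    stopf("fuse_pair: image shapes differ (%s vs %s)",
          paste(dim(img1), collapse = "x"), paste(dim(img2), collapse = "x"))
  }
  P <- fuse_pair_raw(img1, img2, params)
  if (quantize) quantize8(P) else P
}

#' The overall fused suture image
#'
#' @param pixels 50x200 numeric matrix in `[0, 255]`.
#' @param subject_id scan identifier.
#' @param n_source number of source ROI slices.
#' @param sharpened whether the sharpening operator was applied.
#' @return an object of class `fused_image`.
#' @export
fused_image <- function(pixels, subject_id = "subject", n_source = 1L,
                        sharpened = FALSE) {
  d <- dim(pixels)
  if (is.null(d) || d[1] != 50 || d[2] != 200) stopf("fused image must be 50x200")
  if (min(pixels) < 0 || max(pixels) > 255) stopf("fused values must lie in [0, 255]")
  if (n_source < 1) stopf("a fused image needs >= 1 source slices")
  structure(list(pixels = pixels, subject_id = as.character(subject_id),
                 n_source = as.integer(n_source), sharpened = isTRUE(sharpened)),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("<fused_image> %s: 50x200 from %d slices%s\n", x$subject_id,
              x$n_source, if (x$sharpened) ", sharpened" else ""))
  invisible(x)
}

#' Fuse a multi-slice ROI stack into one image by pairwise merging
#'
#' Fusing all slices by a single direct average would pull every pixel
#' towards the mean gray level and blur the suture. Instead the stack is
#' merged like a tournament: the current list of images is partitioned into
#' consecutive pairs, each pair is fused with [fuse_pair()], an odd trailing
#' image is carried to the next round unchanged, and rounds repeat until a
#' single image remains -- exactly `n - 1` pair fusions in `ceiling(log2(n))`
#' rounds (O(n log n) work). Intermediate rounds are kept in floating point;
#' quantization to 8 bits happens once at the end. If
#' `params$sharpen_strength > 0` the result is sharpened with [sharpen()].
#'
#' @param stack a [slice_stack()] (or a plain list of equal-shaped
#'   matrices).
#' @param params a [fusion_params()] object.
#' @return a [fused_image()]; attribute `n_pair_fusions` records the number
#'   of pair fusions executed.
#' @export
fuse_stack <- function(stack, params = fusion_params()) {
  if (inherits(stack, "slice_stack")) {
    imgs <- stack$images
    sid <- stack$subject_id
  } else {
    imgs <- stack
    sid <- "subject"
  }
  if (!length(imgs)) stopf("cannot fuse an empty stack")
  n <- length(imgs)
  n_fusions <- 0L
  while (length(imgs) > 1) {
    nxt <- vector("list", ceiling(length(imgs) / 2))
    for (i in seq_along(nxt)) {
      a <- 2L * i - 1L; b <- 2L * i
      if (b <= length(imgs)) {
        nxt[[i]] <- fuse_pair(imgs[[a]], imgs[[b]], params, quantize = FALSE)
        n_fusions <- n_fusions + 1L
      } else {
        nxt[[i]] <- imgs[[a]]                   # odd trailing image carried
      }
    }
    imgs <- nxt
  }
  out <- imgs[[1]]
  sharpened <- params$sharpen_strength > 0
  if (sharpened) out <- sharpen(out, params$sharpen_strength)
  out <- quantize8(out)
  res <- fused_image(out, subject_id = sid, n_source = n, sharpened = sharpened)
  attr(res, "n_pair_fusions") <- n_fusions
  res
}

#' Unsharp (Laplacian) sharpening
#'
#' Convolves the image with the kernel
#' `[[0, -k, 0], [-k, 1 + 4k, -k], [0, -k, 0]]` (identity minus `k` times
#' the 4-neighbour Laplacian), replicating edge pixels, then clips to
#' `[0, 255]`. The kernel sums to 1, so flat fields pass through unchanged;
#' `k = 0` is the identity.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param k non-negative sharpening weight.
#' @return a matrix of the same shape (not quantized).
#' @export
sharpen <- function(img, k) {
  if (k < 0) stopf("sharpen weight k must be >= 0")
  if (k == 0) return(img)
  kernel <- matrix(c(0, -k, 0, -k, 1 + 4 * k, -k, 0, -k, 0), 3, 3)
  clip255(conv2_replicate(img, kernel))
}

#' Direct all-at-once fusion (for comparison)
#'
#' Averages all slices in one step and applies the contrast enhancement
#' once. On heterogeneous stacks this pulls pixels towards the mean gray
#' level, producing a flatter (lower-variance) image than the pairwise merge
#' of [fuse_stack()] -- the motivation for merging in pairs.
#'
#' @inheritParams fuse_stack
#' @return a [fused_image()].
#' @export
fuse_direct <- function(stack, params = fusion_params()) {
  if (inherits(stack, "slice_stack")) {
    imgs <- stack$images
    sid <- stack$subject_id
  } else {
    imgs <- stack
    sid <- "subject"
  }
  if (!length(imgs)) stopf("cannot fuse an empty stack")
  A <- Reduce(`+`, imgs) / length(imgs)
  e <- mean(A)
  d <- if (params$d_mode == "max") {
    max(vapply(imgs, function(im) max(abs(im - A)), numeric(1)))
  } else params$d_fixed
  P <- A * (1 + (A - e) / (255 + d))
  if (params$clip) P <- clip255(P)
  sharpened <- params$sharpen_strength > 0
  if (sharpened) P <- sharpen(P, params$sharpen_strength)
  fused_image(quantize8(P), subject_id = sid, n_source = length(imgs),
              sharpened = sharpened)
}
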