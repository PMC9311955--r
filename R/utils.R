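#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-subject seed from a root seed; kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 10007 + as.double(i) * 97 + 1) %% 2147483629)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

## Round half up (2.5 -> 3), the quantization convention for 8-bit output.
round_half_up <- function(x) floor(x + 0.5)

quantize8 <- function(x) {
  storage.mode(x) <- "double"
  y <- round_half_up(clip255(x))
  y
}

is_image_8bit <- function(img) {
  is.matrix(img) && is.numeric(img) && all(img >= 0) && all(img <= 255)
}

#' Bilinear sampling of a matrix at continuous coordinates
#'
#' Coordinates are 0-based continuous pixel indices (0 is the centre of the
#' first pixel). Out-of-range coordinates are clamped, i.e. edges replicate.
#'
#' @param img numeric matrix.
#' @param r,c equal-length numeric vectors of row/column coordinates.
#' @return numeric vector of sampled values, same length as `r`.
#' @noRd
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 0), H - 1)
  c <- pmin(pmax(c, 0), W - 1)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;  fc <- c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  ## 1-based linear indices of the four corners
  i00 <- r0 + 1 + H * c0
  i10 <- r1 + 1 + H * c0
  i01 <- r0 + 1 + H * c1
  i11 <- r1 + 1 + H * c1
  v <- img[i00] * (1 - fr) * (1 - fc) +
    img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc +
    img[i11] * fr * fc
  v
}

#' Resize a matrix with bilinear interpolation (edge-aligned convention)
#'
#' Output pixel centre `k` (0-based) maps to source coordinate
#' `(k + 0.5) * size_in / size_out - 0.5`, the standard image-resize grid, so
#' halving a dimension maps each output pixel to exactly 0.5 source pixels.
#' @noRd
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  rc <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  cc <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  r <- rep(rc, times = out_w)
  c <- rep(cc, each = out_h)
  matrix(bilinear_sample(img, r, c), nrow = out_h, ncol = out_w)
}

## Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(img, p) {
  if (p == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  ri <- c(rep(1, p), seq_len(H), rep(H, p))
  ci <- c(rep(1, p), seq_len(W), rep(W, p))
  img[ri, ci, drop = FALSE]
}

#' 2-D convolution with a small kernel, replicate edges
#'
#' Correlation-style application (kernel not flipped; all kernels used in the
#' package are symmetric). Edge pixels are replicated before the sum.
#' @noRd
conv2_replicate <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  p <- max(ph, pw)
  xp <- pad_replicate(img, p)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * xp[(p - ph + a - 1) + seq_len(H),
                          (p - pw + b - 1) + seq_len(W), drop = FALSE]
    }
  }
  out
}
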