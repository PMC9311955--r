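#' Ordered stack of normalized suture ROI images
#'
#' @param images list of 50x200 numeric matrices (8-bit gray), ordered from
#'   the upper to the lower axial slice.
#' @param subject_id scan identifier.
#' @return an object of class `slice_stack`.
#' @export
slice_stack <- function(images, subject_id = "subject") {
  if (!length(images)) stopf("a slice stack needs at least one image")
  for (i in seq_along(images)) {
    d <- dim(images[[i]])
    if (is.null(d) || d[1] != 50 || d[2] != 200) {
      stopf("ROI image %d is not 50x200", i)
    }
    if (min(images[[i]]) < 0 || max(images[[i]]) > 255) {
      stopf("ROI image %d has values outside [0, 255]", i)
    }
  }
  structure(list(images = images, subject_id = as.character(subject_id),
                 n_slices = length(images)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %s: %d ROI slices of 50x200\n", x$subject_id, x$n_slices))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) x$n_slices

#' Extract the normalized 50x200 suture ROI stack from a volume
#'
#' For each axial slice in `[upper_slice, lower_slice)` the window centred
#' left-right on `midline_px` and spanning 50 px transversely is cropped
#' exactly (columns `midline_px - 24` to `midline_px + 25`, 0-based), while
#' the anterior-posterior extent `[anterior_px, posterior_px)` is resampled
#' to 200 px with bilinear interpolation. Output images are 50 rows
#' (transverse, across the suture) by 200 columns (anterior-posterior) with
#' the anterior end at column 0. The resampling grid is edge-aligned:
#' output column `k` (0-based) samples source row
#' `anterior_px + (k + 0.5) * span / 200 - 0.5`, so a 100-px span maps each
#' output column to exactly 0.5 source pixels. Bilinear interpolation is
#' convex, so no resampling overshoot can leave `[0, 255]`.
#'
#' @param volume a [volume_grid()].
#' @param bounds a [roi_boundaries()] valid for `volume`.
#' @return a [slice_stack()] with `lower_slice - upper_slice` images.
#' @export
extract_roi <- function(volume, bounds) {
  stopifnot(inherits(volume, "volume_grid"), inherits(bounds, "roi_boundaries"))
  d <- dim(volume$voxels)
  if (bounds$lower_slice > d[3]) {
    stopf("subject %s: slice range [%d,%d) exceeds the %d-slice volume",
          bounds$subject_id, bounds$upper_slice, bounds$lower_slice, d[3])
  }
  col_start <- bounds$midline_px - 24L          # 0-based; 50-px window
  if (col_start < 0 || col_start + 49L > 511L) {
    stopf("subject %s: 50-px transverse window around midline %d exceeds the 512-px frame",
          bounds$subject_id, bounds$midline_px)
  }
  if (bounds$posterior_px > 512L) {
    stopf("subject %s: anterior-posterior range exceeds the 512-px frame",
          bounds$subject_id)
  }
  span <- bounds$posterior_px - bounds$anterior_px
  ## edge-aligned source row coordinates (0-based, within the full frame)
  src_rows <- bounds$anterior_px + (seq_len(200) - 0.5) * span / 200 - 0.5
  src_rows <- pmin(pmax(src_rows, bounds$anterior_px),
                   bounds$posterior_px - 1)
  r0 <- floor(src_rows); fr <- src_rows - r0
  r1 <- pmin(r0 + 1, bounds$posterior_px - 1)
  cols <- (col_start + 1L):(col_start + 50L)    # 1-based volume columns
  images <- vector("list", bounds$lower_slice - bounds$upper_slice)
  for (s in seq_along(images)) {
    sl <- volume$voxels[, cols, bounds$upper_slice + s, drop = FALSE]
    dim(sl) <- c(512, 50)
    ## linear interpolation along rows, then transpose: anterior -> column 0
    roi <- sl[r0 + 1, , drop = FALSE] * (1 - fr) + sl[r1 + 1, , drop = FALSE] * fr
    images[[s]] <- t(roi)
  }
  slice_stack(images, subject_id = bounds$subject_id)
}

#' Export per-slice ROI images as PNG files
#'
#' Writes one PNG per slice named `<subject>_sliceNNN.png` for expert
#' review.
#'
#' @param stack a [slice_stack()].
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
export_roi_pngs <- function(stack, dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(stack$n_slices)
  for (s in seq_len(stack$n_slices)) {
    paths[s] <- file.path(dir, sprintf("%s_slice%03d.png", stack$subject_id, s - 1))
    save_png(round_half_up(stack$images[[s]]), paths[s])
  }
  invisible(paths)
}
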