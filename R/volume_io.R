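#' CBCT volume container
#'
#' A `volume_grid` holds one CBCT scan as an 8-bit gray voxel array of
#' dimension `c(512, 512, n_axial)`: rows run along the anterior-posterior
#' axis, columns along the transverse (left-right) axis, and the third index
#' over axial slices. Voxel spacing defaults to the 0.3 mm isotropic
#' resolution typical of dental CBCT.
#'
#' @param voxels numeric array `c(512, 512, n_axial)` with values in
#'   `[0, 255]`.
#' @param spacing_mm positive length-3 numeric, voxel spacing in mm
#'   (row, column, axial).
#' @param subject_id opaque subject/scan identifier.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing_mm = c(0.3, 0.3, 0.3),
                        subject_id = "subject") {
  if (length(dim(voxels)) != 3) stopf("voxels must be a 3-D array")
  d <- dim(voxels)
  if (d[1] != 512 || d[2] != 512) {
    stopf("in-plane resolution must be 512x512, got %dx%d", d[1], d[2])
  }
  if (d[3] < 1) stopf("volume needs at least one axial slice")
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 255) {
    stopf("voxel values must lie in [0, 255] with no missing values")
  }
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be three positive numbers")
  }
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 subject_id = as.character(subject_id)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid> %s: %d axial slices of 512x512, spacing %.2f/%.2f/%.2f mm\n",
              x$subject_id, d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$voxels)

#' Suture ROI boundary labels for one scan
#'
#' Expert labels delimiting the midpalatal-suture region inside a CBCT
#' volume, together with the subject's chronological age and sex. All
#' indices are 0-based and ranges are half-open `[lo, hi)`: axial slices
#' `[upper_slice, lower_slice)` span the palatal vault down to the incisor
#' apex, rows `[anterior_px, posterior_px)` span the suture's
#' anterior-posterior extent, and `midline_px` is the in-plane column of the
#' midsagittal line.
#'
#' @param subject_id scan identifier matching the volume.
#' @param upper_slice,lower_slice 0-based axial slice range, half-open.
#' @param anterior_px,posterior_px 0-based in-plane row range, half-open.
#' @param midline_px 0-based in-plane column of the midline.
#' @param age_months chronological age in months; the study design covers
#'   ages 4-23 years, i.e. `[48, 288)` months.
#' @param sex `"F"` or `"M"`.
#' @return an object of class `roi_boundaries`.
#' @export
roi_boundaries <- function(subject_id, upper_slice, lower_slice,
                           anterior_px, posterior_px, midline_px,
                           age_months, sex) {
  upper_slice <- as.integer(upper_slice); lower_slice <- as.integer(lower_slice)
  anterior_px <- as.integer(anterior_px); posterior_px <- as.integer(posterior_px)
  midline_px <- as.integer(midline_px); age_months <- as.integer(age_months)
  if (upper_slice < 0 || upper_slice >= lower_slice) {
    stopf("need 0 <= upper_slice < lower_slice (got %d, %d)", upper_slice, lower_slice)
  }
  if (anterior_px < 0 || anterior_px >= posterior_px) {
    stopf("need 0 <= anterior_px < posterior_px (got %d, %d)", anterior_px, posterior_px)
  }
  if (midline_px < 0 || midline_px > 511) stopf("midline_px out of the 512-px frame")
  if (is.na(age_months) || age_months < 48 || age_months >= 288) {
    stopf("age_months must lie in [48, 288), got %s", age_months)
  }
  if (!sex %in% c("F", "M")) stopf("sex must be 'F' or 'M', got '%s'", sex)
  structure(list(subject_id = as.character(subject_id),
                 upper_slice = upper_slice, lower_slice = lower_slice,
                 anterior_px = anterior_px, posterior_px = posterior_px,
                 midline_px = midline_px, age_months = age_months, sex = sex),
            class = "roi_boundaries")
}

#' @export
print.roi_boundaries <- function(x, ...) {
  cat(sprintf("<roi_boundaries> %s: slices [%d,%d), rows [%d,%d), midline %d, %d mo, %s\n",
              x$subject_id, x$upper_slice, x$lower_slice, x$anterior_px,
              x$posterior_px, x$midline_px, x$age_months, x$sex))
  invisible(x)
}

## Min-max window raw intensities to 8-bit gray. A constant volume (zero
## dynamic range) maps to all-zero by convention.
window_to_8bit <- function(raw, window = NULL) {
  raw <- as.numeric(raw)
  if (is.null(window)) {
    lo <- min(raw); hi <- max(raw)
  } else {
    lo <- window[1]; hi <- window[2]
  }
  if (hi <= lo) return(raw * 0)
  round_half_up(clip255((raw - lo) / (hi - lo) * 255))
}

#' Read a CBCT volume
#'
#' Reads a volume from a NIfTI file (`.nii` / `.nii.gz`) and windows the raw
#' intensities to 8-bit gray. The default window is the per-volume min-max
#' rescale to `[0, 255]` (the fusion arithmetic assumes a 255 gray range); a
#' fixed window can be supplied instead. Windowing is monotone, so voxel
#' order statistics are preserved. A `uint8` source is already windowed
#' gray and passes through bit-identically, which makes
#' [write_volume()]/[read_volume()] a lossless round trip.
#'
#' DICOM series directories are not a supported input of this package;
#' convert the series to NIfTI first.
#'
#' @param path path to a NIfTI file.
#' @param window `NULL` for per-volume min-max, or `c(lo, hi)` for a fixed
#'   window (values clipped).
#' @param subject_id identifier; defaults to the file name.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, window = NULL, subject_id = NULL) {
  if (dir.exists(path)) {
    stopf(paste0("'%s' is a directory; DICOM series input is not supported, ",
                 "convert the series to NIfTI (.nii/.nii.gz) first"), path)
  }
  if (!file.exists(path)) stopf("volume file '%s' does not exist", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", path))
  if (!grepl("\\.nii(\\.gz)?$", tolower(path))) {
    stopf("unsupported volume container '%s' (expected .nii or .nii.gz)", ext)
  }
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3) stopf("'%s' is not a 3-D volume", path)
  if (anyNA(arr)) stopf("'%s' contains missing voxels (corrupt slice data)", path)
  if (is.null(window)) {
    ## uint8 sources are already windowed gray: pass through bit-identically
    ## (the on-disk datatype lives in the file header, code 2 = uint8)
    dt <- tryCatch(RNifti::niftiHeader(path)$datatype, error = function(e) NA)
    if (identical(as.integer(dt), 2L)) window <- c(0, 255)
  }
  vox <- array(window_to_8bit(arr, window), dim = dim(arr))
  sp <- tryCatch(RNifti::pixdim(nii)[1:3], error = function(e) c(0.3, 0.3, 0.3))
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(0.3, 0.3, 0.3)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  volume_grid(vox, spacing_mm = sp, subject_id = subject_id)
}

#' Write a volume to a NIfTI file
#'
#' Stores the 8-bit voxel array losslessly (`uint8` datatype); reading the
#' file back with [read_volume()] reproduces the voxels bit-identically.
#'
#' @param vol a [volume_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  vox <- vol$voxels
  attr(vox, "pixdim") <- vol$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(vox), path, datatype = "uint8")
  invisible(path)
}

labels_schema <- c("subject_id", "upper_slice", "lower_slice", "anterior_px",
                   "posterior_px", "midline_px", "age_months", "sex")

#' Read ROI boundary labels from CSV
#'
#' The label file is a CSV with header
#' `subject_id,upper_slice,lower_slice,anterior_px,posterior_px,midline_px,age_months,sex`,
#' one row per scan. Rows violating the [roi_boundaries()] invariants are
#' rejected with their row number.
#'
#' @param path CSV path.
#' @return a list of [roi_boundaries()] records.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("labels file '%s' does not exist", path)
  ## sex codes "F"/"M" must never be parsed as logicals
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sex = "character"))
  missing <- setdiff(labels_schema, names(df))
  if (length(missing)) {
    stopf("labels file '%s' lacks columns: %s", path, paste(missing, collapse = ", "))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      roi_boundaries(df$subject_id[i], df$upper_slice[i], df$lower_slice[i],
                     df$anterior_px[i], df$posterior_px[i], df$midline_px[i],
                     df$age_months[i], df$sex[i]),
      error = function(e) stopf("labels row %d: %s", i, conditionMessage(e)))
  }
  out
}

#' Write ROI boundary labels to CSV
#'
#' @param labels a list of [roi_boundaries()] records, or a data.frame with
#'   the schema columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (is.data.frame(labels)) {
    df <- labels[, labels_schema]
  } else {
    df <- do.call(rbind, lapply(labels, function(b) {
      as.data.frame(b[labels_schema], stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save an 8-bit grayscale image as PNG
#' @param img numeric matrix with values in `[0, 255]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  stopifnot(is_image_8bit(img))
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a PNG as an 8-bit grayscale matrix
#' @param path PNG path.
#' @return numeric matrix with values in `[0, 255]`.
#' @export
load_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round_half_up(a * 255)
}
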