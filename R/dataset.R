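#' Five-class age-range label
#'
#' Maps chronological age to the five study age ranges: 4-10 years -> 0,
#' 11-12 -> 1, 13-14 -> 2, 15-16 -> 3, 17-23 -> 4 (completed years,
#' `floor(age_months / 12)`).
#'
#' @param age_months integer vector of ages in months, within the study
#'   range `[48, 288)`.
#' @return integer vector of labels 0-4.
#' @export
label_of <- function(age_months) {
  age_months <- as.integer(age_months)
  if (anyNA(age_months) || any(age_months < 48) || any(age_months >= 288)) {
    stopf("age_months outside the study range [48, 288)")
  }
  years <- age_months %/% 12L
  unname(c(`4` = 0L, `5` = 0L, `6` = 0L, `7` = 0L, `8` = 0L, `9` = 0L, `10` = 0L,
           `11` = 1L, `12` = 1L, `13` = 2L, `14` = 2L, `15` = 3L, `16` = 3L,
           `17` = 4L, `18` = 4L, `19` = 4L, `20` = 4L, `21` = 4L, `22` = 4L,
           `23` = 4L)[as.character(years)])
}

#' Age bounds of the five labels
#' @return a data.frame with `label`, `lo_years`, `hi_years` (inclusive).
#' @export
age_range_bounds <- function() {
  data.frame(label = 0:4, lo_years = c(4, 11, 13, 15, 17),
             hi_years = c(10, 12, 14, 16, 23))
}

#' Augmentation policy
#'
#' Magnitudes of the six small-amplitude training-set augmentations:
#' random translation, tilt, contrast and brightness adjustment, cropping,
#' and horizontal mirroring. Defaults keep every transform within 10% of
#' the image extent / intensity range.
#'
#' @param translate_frac maximum shift as a fraction of each image extent.
#' @param tilt_deg maximum rotation in degrees.
#' @param contrast_frac maximum relative contrast change.
#' @param brightness_frac maximum brightness shift as a fraction of 255.
#' @param crop_frac maximum cropped margin as a fraction of each extent.
#' @param hflip_prob probability of horizontal mirroring.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(translate_frac = 0.05, tilt_deg = 5,
                                contrast_frac = 0.10, brightness_frac = 0.10,
                                crop_frac = 0.05, hflip_prob = 0.5) {
  vals <- c(translate_frac, tilt_deg, contrast_frac, brightness_frac, crop_frac)
  if (any(vals < 0)) stopf("augmentation magnitudes must be non-negative")
  if (hflip_prob < 0 || hflip_prob > 1) stopf("hflip_prob must lie in [0, 1]")
  structure(list(translate_frac = translate_frac, tilt_deg = tilt_deg,
                 contrast_frac = contrast_frac, brightness_frac = brightness_frac,
                 crop_frac = crop_frac, hflip_prob = hflip_prob),
            class = "augmentation_policy")
}

## Rotate about the image centre by `deg`, bilinear, replicate edges.
rotate_image <- function(img, deg) {
  if (deg == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- deg * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  r <- rep(seq_len(H) - 1, times = W) - cy
  c <- rep(seq_len(W) - 1, each = H) - cx
  ## inverse mapping: output (r, c) samples source rotated by -theta
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  matrix(bilinear_sample(img, sr, sc), H, W)
}

## Integer shift with replicate edges.
shift_image <- function(img, dr, dc) {
  if (dr == 0 && dc == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H) - dr, 1), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1), W)
  img[ri, ci, drop = FALSE]
}

#' Randomly augment a 50x200 suture image
#'
#' Applies, in order: integer translation (replicate edges), tilt
#' (rotation about the centre, bilinear), centre-out random crop followed
#' by resize back, contrast scaling about the image mean, brightness shift,
#' and horizontal mirroring. Magnitudes are drawn uniformly within the
#' policy bounds; the output is re-normalized to 50x200 and clipped to
#' `[0, 255]`. Deterministic given the seed.
#'
#' @param img 50x200 numeric matrix in `[0, 255]`.
#' @param policy an [augmentation_policy()].
#' @param seed integer RNG seed.
#' @return an augmented 50x200 matrix (8-bit quantized).
#' @export
augment <- function(img, policy = augmentation_policy(), seed = 1) {
  d <- dim(img)
  if (is.null(d) || d[1] != 50 || d[2] != 200) stopf("augment expects a 50x200 image")
  with_seed(seed, {
    out <- img
    ## translation: integer pixel shift up to the fractional extent
    if (policy$translate_frac > 0) {
      mr <- floor(policy$translate_frac * 50)
      mc <- floor(policy$translate_frac * 200)
      out <- shift_image(out, sample(-mr:mr, 1), sample(-mc:mc, 1))
    }
    if (policy$tilt_deg > 0) {
      out <- rotate_image(out, stats::runif(1, -policy$tilt_deg, policy$tilt_deg))
    }
    if (policy$crop_frac > 0) {
      kr <- sample(0:floor(policy$crop_frac * 50), 1)
      kc <- sample(0:floor(policy$crop_frac * 200), 1)
      if (kr > 0 || kc > 0) {
        out <- out[(1 + kr):(50 - kr), (1 + kc):(200 - kc), drop = FALSE]
        out <- resize_bilinear(out, 50, 200)
      }
    }
    if (policy$contrast_frac > 0) {
      g <- 1 + stats::runif(1, -policy$contrast_frac, policy$contrast_frac)
      out <- mean(out) + g * (out - mean(out))
    }
    if (policy$brightness_frac > 0) {
      out <- out + stats::runif(1, -policy$brightness_frac, policy$brightness_frac) * 255
    }
    if (policy$hflip_prob > 0 && stats::runif(1) < policy$hflip_prob) {
      out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
    }
    quantize8(out)
  })
}

#' Stratified grouped train/validation/test splits
#'
#' Selects `val_per_class` validation and `test_per_class` test records per
#' age-range label, the remainder forming the training set. Selection is
#' seeded stratified sampling standing in for the expert-curated "typical"
#' samples of the study design; an explicit `curated` list of subject_ids
#' may override the sampled validation/test membership. When the same
#' participant contributes several scans, all of their records stay on the
#' same side of the split (no subject leakage): validation/test quotas are
#' filled from participants whose records all carry the same label and
#' whose full record set fits the remaining quota.
#'
#' @param records data.frame with `subject_id`, `label` (or `age_months`),
#'   and optionally `participant_id` (defaults to `subject_id`).
#' @param val_per_class,test_per_class records per class in the validation
#'   and test sets (defaults 10 and 20, i.e. 50 and 100 records for five
#'   classes).
#' @param seed integer RNG seed; the same seed reproduces the same splits.
#' @param curated optional character vector of subject_ids to force into
#'   the validation/test pool before sampling.
#' @return a list with integer row-index vectors `train`, `val`, `test`
#'   (a partition of `seq_len(nrow(records))`) and the `seed`.
#' @export
make_splits <- function(records, val_per_class = 10L, test_per_class = 20L,
                        seed = 1, curated = NULL) {
  if (!"label" %in% names(records)) {
    if (!"age_months" %in% names(records)) {
      stopf("records need a 'label' or 'age_months' column")
    }
    records$label <- label_of(records$age_months)
  }
  pid <- if ("participant_id" %in% names(records)) {
    as.character(records$participant_id)
  } else as.character(records$subject_id)
  lab <- as.integer(records$label)
  n <- nrow(records)
  taken <- rep(FALSE, n)
  pick_class <- function(cl, quota, allowed) {
    ## participants all of whose records have label cl and are still free
    idx <- which(lab == cl & !taken & allowed)
    if (!length(idx)) idx <- integer(0)
    parts <- unique(pid[idx])
    pure <- parts[vapply(parts, function(p) {
      all(lab[pid == p] == cl) && !any(taken[pid == p])
    }, logical(1))]
    pure <- sample(pure)
    chosen <- integer(0)
    for (p in pure) {
      ridx <- which(pid == p)
      if (length(chosen) + length(ridx) <= quota) {
        chosen <- c(chosen, ridx)
        if (length(chosen) == quota) break
      }
    }
    if (length(chosen) < quota) {
      stopf("class %d: cannot select %d leakage-free records (only %d available)",
            cl, quota, length(chosen))
    }
    chosen
  }
  with_seed(seed, {
    allowed <- if (is.null(curated)) rep(TRUE, n) else {
      as.character(records$subject_id) %in% curated
    }
    val <- integer(0); test <- integer(0)
    for (cl in sort(unique(lab))) {
      v <- pick_class(cl, val_per_class, allowed); taken[v] <- TRUE
      val <- c(val, v)
      t <- pick_class(cl, test_per_class, allowed); taken[t] <- TRUE
      test <- c(test, t)
    }
    train <- setdiff(seq_len(n), c(val, test))
    list(train = sort(train), val = sort(val), test = sort(test),
         seed = as.integer(seed))
  })
}

#' Write a split manifest as JSON
#'
#' Records the subject_ids of each split together with the seed, so a run
#' can be reproduced exactly.
#'
#' @param splits result of [make_splits()].
#' @param records the record table the splits index into.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, records, path) {
  manifest <- list(seed = splits$seed,
                   train = records$subject_id[splits$train],
                   val = records$subject_id[splits$val],
                   test = records$subject_id[splits$test])
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
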