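#' Parameters of the synthetic midpalatal-suture phantom
#'
#' The phantom emulates the structure of a clinical CBCT database: stacks of
#' 512x512 axial slices containing a sinuous midpalatal-suture band whose
#' appearance is driven by a latent ossification parameter `omega` in
#' `[0, 1]`. A young suture (`omega = 0`) is wide, dark, internally speckled
#' and jagged-edged; as `omega` rises, the internal speckle (unossified
#' interdigitation gaps) fills in linearly while the overall intensity
#' deficit of the gap decays more slowly (as `sqrt(1 - omega)`, the way
#' bony bridges form before the gap closes completely), the edge jaggedness
#' and width shrink, and at `omega = 1` the band is iso-intense with bone
#' and statistically indistinguishable from it. The surrounding bone
#' texture (a smooth low-frequency anatomical field plus fine per-slice
#' acquisition noise) does not depend on `omega`, so all age-discriminative
#' signal is localized at the suture.
#'
#' @param omega latent ossification parameter in `[0, 1]`.
#' @param age_months chronological age in months; if `NULL`, mapped from
#'   `omega` as `48 + omega * 228` (4 y at `omega = 0`, 23 y at `omega = 1`).
#' @param sex `"F"` or `"M"`.
#' @param n_slices number of axial slices containing the suture.
#' @param suture_width_px transverse full width of the band at `omega = 0`,
#'   in px; the effective width is `suture_width_px - 8 * omega`.
#' @param suture_contrast intensity deficit of the band at `omega = 0`
#'   (gray levels); the effective deficit is
#'   `suture_contrast * sqrt(1 - omega)`.
#' @param interdigitation_amplitude amplitude (px) of the sinusoidal
#'   meander of the suture path.
#' @param band_noise_sd gray-level s.d. of the speckle inside the band at
#'   `omega = 0`, scaled by `(1 - omega)`.
#' @param bone_noise_sd gray-level s.d. of the fine bone granularity
#'   (independent of `omega`).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @param subject_id identifier for the generated records.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(omega, age_months = NULL, sex = "F", n_slices = 8,
                           suture_width_px = 20, suture_contrast = 25,
                           interdigitation_amplitude = 5, band_noise_sd = 16,
                           bone_noise_sd = 1.5, seed = 1,
                           subject_id = "phantom") {
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0 || omega > 1) {
    stopf("omega must be a single value in [0, 1]")
  }
  if (is.null(age_months)) age_months <- round(48 + omega * 228)
  age_months <- min(max(as.integer(age_months), 48L), 287L)
  if (n_slices < 1) stopf("n_slices must be >= 1")
  structure(list(omega = omega, age_months = age_months, sex = sex,
                 n_slices = as.integer(n_slices),
                 suture_width_px = suture_width_px,
                 suture_contrast = suture_contrast,
                 interdigitation_amplitude = interdigitation_amplitude,
                 band_noise_sd = band_noise_sd,
                 bone_noise_sd = bone_noise_sd,
                 seed = as.integer(seed),
                 subject_id = as.character(subject_id)),
            class = "phantom_params")
}

## Smooth low-frequency bone field: coarse white noise upsampled bilinearly.
## The coarse grid is fine enough (48 cells across the frame) that ROI-scale
## averages of the field are stable from phantom to phantom.
smooth_field <- function(H, W, coarse = 48, sd = 8) {
  resize_bilinear(matrix(stats::rnorm(coarse * coarse, sd = sd), coarse, coarse), H, W)
}

#' Generate one synthetic CBCT phantom volume with labels
#'
#' Builds a `n_slices` stack of 512x512 axial slices: a bone-textured field
#' (a smooth low-frequency anatomical component plus fine per-slice
#' acquisition noise around gray level 175) with a sinuous dark suture band
#' running along the anterior-posterior (row) axis near the midline column.
#' The anatomy -- smooth field, suture path and the interdigitation speckle
#' pattern inside the band -- is shared across slices (the same palate is
#' imaged in each slice); only the acquisition noise and a small path
#' jitter differ slice to slice. The band's intensity deficit is
#' `suture_contrast * sqrt(1 - omega)` with a Gaussian transverse profile
#' and internal speckle of s.d. `band_noise_sd * (1 - omega)`. Boundary
#' labels are derived from the construction geometry.
#'
#' @param params a [phantom_params()] object.
#' @return a list with elements `volume` (a [volume_grid()]) and `bounds`
#'   (a [roi_boundaries()]).
#' @export
generate_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  with_seed(p$seed, {
    H <- 512L; W <- 512L; ns <- p$n_slices
    anterior <- 106L; posterior <- 406L         # suture row extent, half-open
    rows <- anterior:(posterior - 1L)
    nr <- length(rows)
    midline <- 256L + sample(-6:6, 1)
    bone_level <- 175
    deficit <- p$suture_contrast * sqrt(1 - p$omega)
    speckle_sd <- p$band_noise_sd * (1 - p$omega)
    jag_amp <- 2.5 * (1 - p$omega)
    width <- max(p$suture_width_px - 8 * p$omega, 3)
    sigma <- width / 2
    lambda <- stats::runif(1, 90, 150)          # meander wavelength, px
    phase <- stats::runif(1, 0, 2 * pi)
    ## anatomy shared across slices: the same palate is imaged in every
    ## slice, so the smooth bone field, the jagged path component and the
    ## interdigitation speckle pattern are frozen per subject; only fine
    ## acquisition noise and a small path jitter vary slice to slice
    jag <- jag_amp * as.vector(stats::filter(stats::rnorm(nr), rep(1 / 3, 3),
                                             circular = TRUE))
    anatomy <- bone_level + smooth_field(H, W, sd = 7)
    K <- 20L                                     # half-window across the band
    off <- -K:K
    speckle <- matrix(stats::rnorm(nr * length(off), sd = speckle_sd), nrow = nr)
    vox <- array(0, dim = c(H, W, ns))
    for (s in seq_len(ns)) {
      slice <- anatomy + matrix(stats::rnorm(H * W, sd = p$bone_noise_sd), H, W)
      ## suture path for this slice: sinusoid + jag + small slice jitter
      ## (adjacent axial slices image almost the same palate anatomy, so
      ## the path drifts only slightly from slice to slice)
      centre <- midline + p$interdigitation_amplitude *
        sin(2 * pi * (rows - anterior) / lambda + phase + 0.04 * s) +
        jag + stats::rnorm(1, sd = 0.15)
      if (deficit > 0 || speckle_sd > 0) {
        ci <- round(centre)
        colm <- outer(ci, off, "+")             # nr x (2K+1) column indices
        wgt <- exp(-((colm - centre)^2) / (2 * sigma^2))
        val <- (-deficit + speckle) * wgt
        ok <- colm >= 1 & colm <= W
        idx <- cbind(rep(rows + 1L, times = length(off))[ok], colm[ok])
        slice[idx] <- slice[idx] + val[ok]
      }
      vox[, , s] <- slice
    }
    vox <- round_half_up(clip255(vox))
    vol <- volume_grid(vox, subject_id = p$subject_id)
    bounds <- roi_boundaries(p$subject_id, upper_slice = 0, lower_slice = ns,
                             anterior_px = anterior, posterior_px = posterior,
                             midline_px = midline, age_months = p$age_months,
                             sex = p$sex)
    ## construction truth: slice-averaged suture path (volume column
    ## coordinate per anterior-posterior row) and the band half-width
    path <- midline + p$interdigitation_amplitude *
      sin(2 * pi * (rows - anterior) / lambda + phase + 0.04 * (ns + 1) / 2) + jag
    attr(bounds, "suture_path") <- path
    attr(bounds, "suture_sigma") <- sigma
    list(volume = vol, bounds = bounds)
  })
}

#' Generate a labeled phantom cohort
#'
#' Samples a cohort whose age/sex structure follows the package's reference
#' demographic table (see [demographic_reference()]): ages concentrated in
#' the 10-19 y range with a roughly 610:396 female:male ratio. Participants
#' may contribute more than one scan (repeat visits), mirroring a clinical
#' database where the same child is imaged at several ages. The latent
#' ossification parameter is a noisy monotone function of age:
#' `omega = clamp((age_y - 4) / 19 + N(0, 0.06), 0, 1)`.
#'
#' @param n number of scans (records) to generate.
#' @param seed integer RNG seed.
#' @param age_range_months inclusive-exclusive `[lo, hi)` bounds on sampled
#'   ages, in months.
#' @param visit_probs probabilities that a participant contributes
#'   1, 2, ... scans; default mirrors a cohort where ~60% of participants
#'   have a single scan.
#' @return a data.frame with one row per scan: `subject_id`,
#'   `participant_id`, `age_months`, `sex`, `omega`, `label` (five-class age
#'   range, see [label_of()]), and `seed` (per-scan generator seed).
#' @export
generate_cohort <- function(n, seed = 1, age_range_months = c(48, 288),
                            visit_probs = c(0.60, 0.355, 0.033, 0.010, 0.002)) {
  stopifnot(n >= 1)
  ref <- demographic_reference()
  with_seed(seed, {
    cells <- rbind(data.frame(year = ref$age_years, sex = "F", w = ref$F),
                   data.frame(year = ref$age_years, sex = "M", w = ref$M))
    cells <- cells[cells$w > 0, ]
    rows <- list(); pid <- 0L
    while (length(rows) < n) {
      pid <- pid + 1L
      nv <- sample.int(length(visit_probs), 1, prob = visit_probs)
      cell <- cells[sample.int(nrow(cells), 1, prob = cells$w), ]
      age <- cell$year * 12L + sample(0:11, 1)
      for (v in seq_len(nv)) {
        if (v > 1) age <- age + sample(2:24, 1)   # repeat visit, months later
        if (age < age_range_months[1] || age >= age_range_months[2]) next
        omega <- min(max((age / 12 - 4) / 19 + stats::rnorm(1, sd = 0.06), 0), 1)
        rows[[length(rows) + 1L]] <-
          data.frame(participant_id = sprintf("P%04d", pid),
                     age_months = as.integer(age), sex = cell$sex,
                     omega = omega, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows[seq_len(n)])
    df$subject_id <- sprintf("S%04d", seq_len(n))
    df$label <- label_of(df$age_months)
    df$seed <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
    df[, c("subject_id", "participant_id", "age_months", "sex", "omega",
           "label", "seed")]
  })
}

#' Phantom parameters for one cohort record
#'
#' @param cohort a data.frame from [generate_cohort()].
#' @param i row index.
#' @param ... overrides passed to [phantom_params()].
#' @return a [phantom_params()] object.
#' @export
phantom_from_cohort <- function(cohort, i, ...) {
  r <- cohort[i, ]
  phantom_params(omega = r$omega, age_months = r$age_months, sex = r$sex,
                 seed = r$seed, subject_id = r$subject_id, ...)
}

#' Fused suture images for a whole cohort
#'
#' Runs the full pipeline for every cohort record: generate the phantom
#' volume, extract the 50x200 ROI stack between the labeled boundaries, and
#' fuse the stack into one image. The workhorse behind trend-recovery tests
#' and classifier experiments.
#'
#' @param cohort a data.frame from [generate_cohort()].
#' @param params a [fusion_params()] object.
#' @param n_slices slices per phantom volume.
#' @return a list with `images` (array `c(50, 200, nrow(cohort))`),
#'   `masks` (logical array of the constructed suture-band region per
#'   image, from [suture_band_mask()]) and `cohort` (the input table).
#' @export
phantom_fused_set <- function(cohort, params = fusion_params(), n_slices = 8) {
  imgs <- array(0, dim = c(50, 200, nrow(cohort)))
  masks <- array(FALSE, dim = c(50, 200, nrow(cohort)))
  for (i in seq_len(nrow(cohort))) {
    ph <- generate_volume(phantom_from_cohort(cohort, i, n_slices = n_slices))
    stack <- extract_roi(ph$volume, ph$bounds)
    imgs[, , i] <- fuse_stack(stack, params)$pixels
    masks[, , i] <- suture_band_mask(ph$bounds)
  }
  list(images = imgs, masks = masks, cohort = cohort)
}

#' Constructed suture-band mask in ROI coordinates
#'
#' Maps the generator's own suture path (construction truth attached to the
#' phantom's boundaries) into the 50x200 ROI frame: for each
#' anterior-posterior column the band covers the rows within `half_width`
#' pixels of the meandering band centre. Used to measure how well heat maps
#' or extracted features localize on the suture.
#'
#' @param bounds a [roi_boundaries()] returned by [generate_volume()]
#'   (carrying the `suture_path` attribute).
#' @param half_width transverse half-width of the band region in px.
#' @return a 50x200 logical matrix (`TRUE` inside the band).
#' @export
suture_band_mask <- function(bounds, half_width = 10) {
  path <- attr(bounds, "suture_path")
  if (is.null(path)) stopf("bounds carry no construction truth (not a phantom?)")
  span <- bounds$posterior_px - bounds$anterior_px
  ## ROI column k (1-based) samples source row anterior + (k - 0.5)*span/200 - 0.5
  src <- (seq_len(200) - 0.5) * span / 200 - 0.5
  src <- pmin(pmax(src, 0), span - 1)
  i0 <- floor(src); fr <- src - i0
  i1 <- pmin(i0 + 1, span - 1)
  centre_col <- path[i0 + 1] * (1 - fr) + path[i1 + 1] * fr
  ## ROI row r corresponds to volume column (midline - 24) + (r - 1), 0-based
  centre_row <- centre_col - bounds$midline_px + 25
  mask <- matrix(FALSE, 50, 200)
  for (k in seq_len(200)) {
    lo <- max(1L, floor(centre_row[k] - half_width))
    hi <- min(50L, ceiling(centre_row[k] + half_width))
    if (lo <= hi) mask[lo:hi, k] <- TRUE
  }
  mask
}
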