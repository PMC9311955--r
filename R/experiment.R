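#' Phantom age-class recovery experiment
#'
#' The desk-scale analogue of the clinical age-range study, run entirely on
#' synthetic phantoms: generate `n` phantom scans at a few widely spaced
#' ossification levels, run the full pipeline (ROI extraction, pairwise
#' merge fusion), train the small residual classifier on
#' photometrically augmented fused images, and evaluate held-out accuracy
#' and Grad-CAM localization against the generator's own suture-band truth
#' masks.
#'
#' Training images receive brightness/contrast jitter and horizontal
#' mirroring only: the fusion step's adaptive contrast enhancement leaks a
#' small amount of global-intensity class information, and photometric
#' jitter removes that shortcut so the classifier must rely on the local
#' suture texture (geometric warps are omitted because they would also
#' displace the localization truth masks).
#'
#' @param n total number of phantom scans (split evenly over `omegas`).
#' @param omegas ossification level of each class.
#' @param test_per_class held-out scans per class.
#' @param steps training steps.
#' @param seed integer RNG seed controlling generation, splitting,
#'   augmentation and training.
#' @param augment_copies augmented copies per training image.
#' @param heat_images how many held-out images to explain with Grad-CAM.
#' @param verbose print training progress.
#' @return a list: `model` (a `suture_cnn`), `accuracy` (held-out),
#'   `report` (an `mps_metrics` for the held-out set), `heat_fractions`
#'   (per explained image, inside the construction-truth band mask),
#'   `mean_heat_fraction`, and the index bookkeeping.
#' @export
phantom_classifier_experiment <- function(n = 300, omegas = c(0.05, 0.5, 0.95),
                                          test_per_class = 20, steps = 300,
                                          seed = 1, augment_copies = 2,
                                          heat_images = 30, verbose = FALSE) {
  k <- length(omegas)
  per <- n %/% k
  cls <- rep(seq_len(k) - 1L, each = per)
  n <- per * k
  imgs <- array(0, dim = c(50, 200, n))
  masks <- array(FALSE, dim = c(50, 200, n))
  for (i in seq_len(n)) {
    p <- phantom_params(omega = omegas[cls[i] + 1L], seed = derive_seed(seed, i),
                        subject_id = sprintf("X%04d", i))
    ph <- generate_volume(p)
    imgs[, , i] <- fuse_stack(extract_roi(ph$volume, ph$bounds))$pixels
    masks[, , i] <- suture_band_mask(ph$bounds)
  }
  ## stratified held-out split
  te <- with_seed(derive_seed(seed, n + 1L), {
    unlist(lapply(seq_len(k) - 1L, function(c) {
      sample(which(cls == c), test_per_class)
    }))
  })
  tr <- setdiff(seq_len(n), te)
  ## photometric augmentation of the training images
  pol <- augmentation_policy(translate_frac = 0, tilt_deg = 0, crop_frac = 0,
                             hflip_prob = 0.5, contrast_frac = 0.10,
                             brightness_frac = 0.10)
  ntr <- length(tr) * augment_copies
  xtr <- array(0, dim = c(50, 200, ntr))
  ytr <- integer(ntr)
  for (j in seq_along(tr)) {
    for (a in seq_len(augment_copies)) {
      jj <- (j - 1L) * augment_copies + a
      xtr[, , jj] <- augment(imgs[, , tr[j]], pol,
                             seed = derive_seed(seed, 2L * n + jj))
      ytr[jj] <- cls[tr[j]]
    }
  }
  spec <- network_spec(blocks = c(1, 1), widths = c(16, 32), block = "basic",
                       stem_channels = 8, stem_kernel = 5, stem_stride = 2,
                       stem_pool = 2, stem_pool_stride = 2, stem_pool_pad = 0,
                       stage_strides = c(2, 1), classes = k)
  config <- train_config(learning_rate = 0.01, max_steps = steps,
                         batch_size = 50, checkpoint_every = 100,
                         select = "best_val", seed = derive_seed(seed, 3L))
  model <- train_cnn(spec, xtr, ytr, imgs[, , te], cls[te], config = config,
                     verbose = verbose)
  probs <- predict(model, imgs[, , te])
  report <- metrics_report(cls[te], scores = probs, n_classes = k)
  ## Grad-CAM localization against the construction truth
  hi <- te[seq_len(min(heat_images, length(te)))]
  heat <- vapply(hi, function(i) {
    heat_band_fraction(gradcam_map(model, imgs[, , i]), masks[, , i])
  }, numeric(1))
  list(model = model, accuracy = report$accuracy, report = report,
       heat_fractions = heat, mean_heat_fraction = mean(heat, na.rm = TRUE),
       test_idx = te, train_idx = tr, classes = cls, omegas = omegas,
       n = n, seed = seed)
}

#' Phantom texture-trend experiment
#'
#' Generates `n` seeded phantoms whose latent ossification parameter
#' sweeps an even grid over `[0, 1]` (the design with maximal power to
#' detect a monotone trend across the whole maturation range), fuses every
#' scan and computes the GLCM features of the fused images, then reports
#' the Spearman rank correlation between the ossification parameter and
#' each feature -- the synthetic counterpart of the clinical observation
#' that homogeneity and correlation rise with chronological age. Ages are
#' mapped monotonically from the ossification parameter, so the per-sex
#' feature-age report mirrors the same trends.
#'
#' @param n number of phantoms across the ossification grid.
#' @param seed integer RNG seed.
#' @param params a [fusion_params()] object.
#' @return a list: `features` (per-scan feature table with `omega`),
#'   `spearman` (named vector over the six features), and `age_report`
#'   (the per-sex feature-age correlation tables).
#' @export
phantom_trend_experiment <- function(n = 200, seed = 1,
                                     params = fusion_params()) {
  omegas <- seq(0, 1, length.out = n)
  meta <- data.frame(subject_id = sprintf("W%04d", seq_len(n)),
                     age_months = pmin(pmax(round(48 + omegas * 228), 48), 287),
                     sex = rep(c("F", "M"), length.out = n),
                     omega = omegas)
  imgs <- array(0, dim = c(50, 200, n))
  for (i in seq_len(n)) {
    p <- phantom_params(omega = omegas[i], age_months = meta$age_months[i],
                        sex = meta$sex[i], seed = derive_seed(seed, i),
                        subject_id = meta$subject_id[i])
    ph <- generate_volume(p)
    imgs[, , i] <- fuse_stack(extract_roi(ph$volume, ph$bounds), params)$pixels
  }
  feats <- texture_feature_table(imgs, meta)
  sp <- vapply(c("correlation", "contrast", "homogeneity", "dissimilarity",
                 "asm", "energy"), function(f) {
    stats::cor(feats$omega, feats[[f]], method = "spearman")
  }, numeric(1))
  list(features = feats, spearman = sp, age_report = age_feature_report(feats))
}
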