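## Shared fixtures built in code; everything is seeded.

## A tiny flat volume with a sentinel-painted block, for localization checks.
sentinel_volume <- function(n_slices = 3, rows = 107:306, midline = 256,
                            sentinel = 10, background = 200) {
  vox <- array(background, dim = c(512, 512, n_slices))
  vox[rows, (midline - 24):(midline + 25) + 1, ] <- sentinel
  volume_grid(vox, subject_id = "sentinel")
}

sentinel_bounds <- function(n_slices = 3, midline = 256) {
  roi_boundaries("sentinel", upper_slice = 0, lower_slice = n_slices,
                 anterior_px = 106, posterior_px = 306, midline_px = midline,
                 age_months = 120, sex = "F")
}

## Direct per-pixel evaluation of the pair-fusion formula (independent of
## the vectorized implementation).
fuse_pair_oracle <- function(img1, img2, d = NULL) {
  A <- matrix(0, nrow(img1), ncol(img1))
  for (i in seq_len(nrow(img1))) {
    for (j in seq_len(ncol(img1))) A[i, j] <- (img1[i, j] + img2[i, j]) / 2
  }
  e <- mean(A)
  if (is.null(d)) d <- max(abs(img1 - img2))
  P <- A
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      P[i, j] <- A[i, j] * (1 + (A[i, j] - e) / (255 + d))
    }
  }
  pmin(pmax(P, 0), 255)
}

## Brute-force GLCM by explicit double loop over pixel pairs.
glcm_oracle <- function(img, levels, dr, dc, symmetric = TRUE, normed = TRUE) {
  H <- nrow(img); W <- ncol(img)
  m <- matrix(0, levels, levels)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
        i <- img[r, c] + 1; j <- img[r2, c2] + 1
        m[i, j] <- m[i, j] + 1
        if (symmetric) m[j, i] <- m[j, i] + 1
      }
    }
  }
  if (normed && sum(m) > 0) m <- m / sum(m)
  m
}

## A quick labeled record table for split tests.
fake_records <- function(per_class, n_classes = 5) {
  ages <- c(60, 132, 156, 180, 240)[seq_len(n_classes)]
  df <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    data.frame(subject_id = sprintf("c%d_%03d", k - 1, seq_len(per_class)),
               age_months = ages[k])
  }))
  df$participant_id <- df$subject_id
  df$label <- label_of(df$age_months)
  df
}

## Small 8-bit test image with reproducible content.
rand_img8 <- function(h, w, seed = 1, levels = 256) {
  set.seed(seed)
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}
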