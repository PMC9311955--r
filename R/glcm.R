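#' GLCM parameters
#'
#' Parameters of the gray-level co-occurrence matrix: number of gray
#' levels, pixel offset distance, the set of offset angles, whether pairs
#' are counted symmetrically (both orderings), and whether each matrix is
#' normalized to sum 1.
#'
#' Angles follow the usual convention for image row/column offsets:
#' 0 degrees pairs each pixel with its right neighbour at the given
#' distance, 90 degrees with the neighbour above, 45/135 degrees with the
#' up-right / up-left diagonals.
#'
#' @param levels number of gray levels (>= 2). Pixel values must be
#'   integers in `[0, levels)`; 8-bit images use the default 256 directly.
#' @param distance positive integer offset in pixels.
#' @param angles numeric vector of angles in degrees, a subset of
#'   `c(0, 45, 90, 135)`.
#' @param symmetric count each pair in both orders (default `TRUE`).
#' @param normed normalize each matrix to sum 1 (default `TRUE`).
#' @return an object of class `glcm_params`.
#' @export
glcm_params <- function(levels = 256L, distance = 1L,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normed = TRUE) {
  levels <- as.integer(levels); distance <- as.integer(distance)
  if (levels < 2) stopf("levels must be >= 2")
  if (distance < 1) stopf("distance must be a positive integer")
  if (!length(angles) || !all(angles %in% c(0, 45, 90, 135))) {
    stopf("angles must be a non-empty subset of {0, 45, 90, 135}")
  }
  structure(list(levels = levels, distance = distance, angles = angles,
                 symmetric = isTRUE(symmetric), normed = isTRUE(normed)),
            class = "glcm_params")
}

## Row/column offsets for each supported angle at distance d.
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stopf("unsupported GLCM angle %s", angle))
}

#' Gray-level co-occurrence matrices
#'
#' Counts ordered (or symmetrized) pairs of gray levels at the given pixel
#' offset, one `levels x levels` matrix per angle. Pixel values are used as
#' level indices directly and must be integers in `[0, levels)`.
#'
#' @param img numeric matrix of integer gray levels in `[0, levels)`.
#' @param params a [glcm_params()] object.
#' @return a named list of `levels x levels` matrices, one per angle
#'   (`"0"`, `"45"`, ...), normalized to sum 1 when `params$normed`.
#' @export
glcm <- function(img, params = glcm_params()) {
  stopifnot(is.matrix(img))
  if (anyNA(img)) stopf("image contains missing values")
  if (any(img != floor(img)) || min(img) < 0 || max(img) >= params$levels) {
    stopf("pixel values must be integers in [0, %d)", params$levels)
  }
  H <- nrow(img); W <- ncol(img); d <- params$distance; L <- params$levels
  if (H <= d || W <= d) {
    stopf("image (%dx%d) is smaller than the %d-px offset", H, W, d)
  }
  out <- vector("list", length(params$angles))
  names(out) <- as.character(params$angles)
  for (a in seq_along(params$angles)) {
    off <- angle_offset(params$angles[a], d)
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(H)[(seq_len(H) + dr) >= 1 & (seq_len(H) + dr) <= H]
    cols <- seq_len(W)[(seq_len(W) + dc) >= 1 & (seq_len(W) + dc) <= W]
    ref <- img[rows, cols, drop = FALSE]
    nbr <- img[rows + dr, cols + dc, drop = FALSE]
    codes <- as.vector(ref) * L + as.vector(nbr) + 1
    counts <- tabulate(codes, nbins = L * L)
    m <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
    if (params$symmetric) m <- m + t(m)
    if (params$normed) {
      s <- sum(m)
      if (s > 0) m <- m / s
    }
    out[[a]] <- m
  }
  out
}

## The six features of one normalized GLCM. Correlation is NA for a
## constant image (zero gray variance).
glcm_features_one <- function(p) {
  L <- nrow(p)
  i <- matrix(rep(0:(L - 1), times = L), L, L)   # row level index
  j <- t(i)
  dif <- i - j
  contrast <- sum(p * dif^2)
  dissimilarity <- sum(p * abs(dif))
  homogeneity <- sum(p / (1 + dif^2))
  asm <- sum(p^2)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum((0:(L - 1)) * pi_); mu_j <- sum((0:(L - 1)) * pj_)
  var_i <- sum((0:(L - 1) - mu_i)^2 * pi_)
  var_j <- sum((0:(L - 1) - mu_j)^2 * pj_)
  correlation <- if (var_i <= 0 || var_j <= 0) NA_real_ else {
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j)
  }
  c(correlation = correlation, contrast = contrast, homogeneity = homogeneity,
    dissimilarity = dissimilarity, asm = asm, energy = sqrt(asm))
}

#' The six GLCM texture features of a suture image
#'
#' Computes, per angle and averaged over angles, the six co-occurrence
#' features used to characterize suture texture:
#' contrast `sum p(i,j) (i-j)^2`, dissimilarity `sum p(i,j) |i-j|`,
#' homogeneity `sum p(i,j) / (1 + (i-j)^2)`, angular second moment
#' `ASM = sum p(i,j)^2`, energy `sqrt(ASM)` (the conventional distinction
#' between the two uniformity measures), and correlation
#' `sum p(i,j)(i - mu_i)(j - mu_j) / (sigma_i sigma_j)`. For a constant
#' image correlation is undefined and returned as `NA` with attribute
#' `correlation_undefined = TRUE`; the other features take their degenerate
#' values (contrast 0, homogeneity 1, ASM 1, ...).
#'
#' @param img numeric matrix of integer gray levels in `[0, levels)`.
#' @param params a [glcm_params()] object.
#' @return a one-row data.frame with the six angle-averaged features;
#'   attribute `per_angle` holds the per-angle feature matrix.
#' @export
texture_features <- function(img, params = glcm_params()) {
  mats <- glcm(img, params)
  per <- vapply(mats, glcm_features_one, numeric(6))
  avg <- rowMeans(per)      # NA propagates if correlation undefined
  out <- as.data.frame(as.list(avg))
  attr(out, "per_angle") <- t(per)
  attr(out, "correlation_undefined") <- anyNA(per["correlation", ])
  out
}

#' Texture features for a set of fused images
#'
#' @param images array `c(50, 200, n)` of fused 8-bit images, or a list of
#'   matrices.
#' @param meta data.frame with `subject_id`, `age_months`, `sex` (one row
#'   per image), e.g. a cohort table.
#' @param params a [glcm_params()] object.
#' @return a data.frame with the metadata columns followed by the six
#'   features.
#' @export
texture_feature_table <- function(images, meta, params = glcm_params()) {
  imgs <- if (is.array(images) && length(dim(images)) == 3) {
    lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  } else images
  if (length(imgs) != nrow(meta)) stopf("images and meta rows differ in length")
  feats <- do.call(rbind, lapply(imgs, texture_features, params = params))
  cbind(meta[, intersect(c("subject_id", "age_months", "sex", "omega"),
                         names(meta)), drop = FALSE], feats)
}

feature_names <- c("correlation", "contrast", "homogeneity", "dissimilarity",
                   "asm", "energy")

#' Feature-age correlation report
#'
#' For each sex group and each of the six texture features, computes the
#' Pearson and Spearman coefficients of feature versus chronological age and
#' returns the scatter data for plotting. Groups with fewer than `min_n`
#' records are skipped with a warning; a feature that is constant within a
#' group gets coefficient 0 with `degenerate = TRUE`.
#'
#' @param features a data.frame from [texture_feature_table()] (needs
#'   `age_months`, `sex`, and the six feature columns).
#' @param min_n minimum group size (default 3).
#' @return a list with `correlations` (data.frame: sex, feature, pearson,
#'   spearman, n, degenerate) and `scatter` (data.frame: sex, feature,
#'   age_months, value).
#' @export
age_feature_report <- function(features, min_n = 3L) {
  rows <- list(); scat <- list()
  for (sx in unique(features$sex)) {
    grp <- features[features$sex == sx, ]
    if (nrow(grp) < min_n) {
      warnf("sex group '%s' has %d < %d records; skipped", sx, nrow(grp), min_n)
      next
    }
    for (f in feature_names) {
      v <- grp[[f]]
      ok <- is.finite(v)
      degenerate <- sum(ok) < min_n || stats::sd(v[ok]) == 0 ||
        stats::sd(grp$age_months[ok]) == 0
      pear <- if (degenerate) 0 else stats::cor(grp$age_months[ok], v[ok])
      spear <- if (degenerate) 0 else {
        stats::cor(grp$age_months[ok], v[ok], method = "spearman")
      }
      rows[[length(rows) + 1L]] <-
        data.frame(sex = sx, feature = f, pearson = pear, spearman = spear,
                   n = sum(ok), degenerate = degenerate)
      scat[[length(scat) + 1L]] <-
        data.frame(sex = sx, feature = f, age_months = grp$age_months[ok],
                   value = v[ok])
    }
  }
  list(correlations = do.call(rbind, rows), scatter = do.call(rbind, scat))
}
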