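# Texture features from gray-level co-occurrence (GLCM), run-length (GLRLM)
# and size-zone (GLSZM) matrices, all computed in 3D.
#
# GLCM: 13 unique direction offsets at distance 1, symmetric; the
# direction-wise normalised matrices are averaged before feature computation.
# GLRLM: features are computed per direction and averaged over the 13
# directions. GLSZM: zones are 26-connected components of equal gray level
# (direction-free). Degenerate single-gray-level ROIs yield defined values
# (no NaN): GLCM correlation is 1, information measures 0.

#' Extract the 53 texture features of an ROI
#'
#' Computes 24 GLCM, 16 GLRLM and 13 GLSZM statistics (IBSI nomenclature)
#' from an equal-width `n_bins`-level discretisation of the ROI intensities.
#'
#' @param image A [volumetric_image] (typically Z-normalised).
#' @param mask An [roi_mask] on the same grid, with at least 2 voxels.
#' @param n_bins Number of gray levels (default 32).
#' @return Named numeric vector of length 53 with names prefixed
#'   `glcm_`, `glrlm_`, `glszm_`.
#' @export
extract_texture <- function(image, mask, n_bins = 32L) {
  assert_that(sum(mask$voxels) >= 2, "ROI must contain at least 2 voxels")
  labels <- suppressWarnings(discretize(image, mask, n_bins))
  texture_from_labels(labels, n_bins)
}

#' Texture features from a precomputed label array
#' @param labels Integer 3D array, 0 outside ROI, `1..n_bins` inside.
#' @param n_bins Number of gray levels.
#' @return Named numeric vector of length 53.
#' @export
texture_from_labels <- function(labels, n_bins = 32L) {
  assert_that(is.array(labels) && length(dim(labels)) == 3L,
              "`labels` must be a 3D integer array")
  np <- sum(labels > 0)
  assert_that(np >= 2, "ROI must contain at least 2 voxels")
  dims <- dim(labels)
  storage.mode(labels) <- "integer"

  glcm_raw <- .cpp_glcm_counts(as.vector(labels), dims, n_bins)
  glrlm_raw <- .cpp_glrlm_counts(as.vector(labels), dims, n_bins)
  glszm <- .cpp_glszm_counts(as.vector(labels), dims, n_bins)

  # average normalised symmetric GLCMs over directions with >=1 pair
  dim(glcm_raw) <- c(n_bins, n_bins, 13L)
  mats <- lapply(seq_len(13L), function(d) {
    m <- matrix(glcm_raw[, , d], n_bins, n_bins)
    tot <- sum(m)
    if (tot > 0) m / tot else NULL
  })
  mats <- Filter(Negate(is.null), mats)
  assert_that(length(mats) > 0, "no co-occurring voxel pairs in ROI")
  P <- Reduce(`+`, mats) / length(mats)
  glcm_feats <- glcm_features(P)

  # GLRLM: per-direction features, averaged
  max_run <- dim(glrlm_raw)[2]
  dim(glrlm_raw) <- c(n_bins, max_run, 13L)
  per_dir <- lapply(seq_len(13L), function(d)
    glrlm_features(matrix(glrlm_raw[, , d], n_bins, max_run), np))
  glrlm_feats <- Reduce(`+`, per_dir) / 13

  glszm_feats <- glszm_features(glszm, np)

  out <- c(stats::setNames(glcm_feats, paste0("glcm_", names(glcm_feats))),
           stats::setNames(glrlm_feats, paste0("glrlm_", names(glrlm_feats))),
           stats::setNames(glszm_feats, paste0("glszm_", names(glszm_feats))))
  stopifnot(length(out) == 53L, all(is.finite(out)))
  out
}

#' @noRd
glcm_features <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  lev <- seq_len(n)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sig_x <- sqrt(sum((lev - mu_x)^2 * px))
  sig_y <- sqrt(sum((lev - mu_y)^2 * py))

  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(n - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * n)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)

  hxy <- ent(P)
  hx <- ent(px)
  hy <- ent(py)
  pxy_prod <- outer(px, py)
  nz <- P > 0 & pxy_prod > 0
  hxy1 <- -sum(P[nz] * log2(pxy_prod[nz]))
  nz2 <- pxy_prod > 0
  hxy2 <- -sum(pxy_prod[nz2] * log2(pxy_prod[nz2]))
  denom <- max(hx, hy)
  imc1 <- if (denom > 0) (hxy - hxy1) / denom else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  corr <- if (sig_x * sig_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sig_x * sig_y) else 1

  off <- i != j
  c(autocorrelation = sum(i * j * P),
    joint_average = mu_x,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(p_diff),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / n)^2)),
    idn = sum(P / (1 + abs(i - j) / n)),
    inverse_variance = sum(P[off] / (i[off] - j[off])^2),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = ent(p_sum),
    sum_variance = sum((k_sum - sa)^2 * p_sum),
    dissimilarity = sum(abs(i - j) * P),
    imc1 = imc1,
    imc2 = imc2)
}

#' Shared features of run-length / size-zone style matrices
#'
#' `M[g, s]` counts runs (zones) of gray level `g` and length (size) `s`;
#' `np` is the ROI voxel count.
#' @noRd
rl_core <- function(M, np) {
  nr <- sum(M)
  g <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  s <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  p <- M / nr
  mg <- rowSums(M)   # per gray level
  ms <- colSums(M)   # per length/size
  mu_g <- sum(g * p)
  mu_s <- sum(s * p)
  pos <- p > 0
  list(nr = nr, g = g, s = s, p = p,
    short = sum(M / s^2) / nr,
    long = sum(M * s^2) / nr,
    gln = sum(mg^2) / nr,
    glnn = sum(mg^2) / nr^2,
    sln = sum(ms^2) / nr,
    slnn = sum(ms^2) / nr^2,
    pct = nr / np,
    glv = sum(p * (g - mu_g)^2),
    sv = sum(p * (s - mu_s)^2),
    entropy = -sum(p[pos] * log2(p[pos])),
    lowg = sum(M / g^2) / nr,
    highg = sum(M * g^2) / nr,
    short_lowg = sum(M / (g^2 * s^2)) / nr,
    short_highg = sum(M * g^2 / s^2) / nr,
    long_lowg = sum(M * s^2 / g^2) / nr,
    long_highg = sum(M * g^2 * s^2) / nr)
}

#' @noRd
glrlm_features <- function(M, np) {
  f <- rl_core(M, np)
  c(short_run_emphasis = f$short,
    long_run_emphasis = f$long,
    gray_level_nonuniformity = f$gln,
    gray_level_nonuniformity_normalized = f$glnn,
    run_length_nonuniformity = f$sln,
    run_length_nonuniformity_normalized = f$slnn,
    run_percentage = f$pct,
    gray_level_variance = f$glv,
    run_variance = f$sv,
    run_entropy = f$entropy,
    low_gray_level_run_emphasis = f$lowg,
    high_gray_level_run_emphasis = f$highg,
    short_run_low_gray_level_emphasis = f$short_lowg,
    short_run_high_gray_level_emphasis = f$short_highg,
    long_run_low_gray_level_emphasis = f$long_lowg,
    long_run_high_gray_level_emphasis = f$long_highg)
}

#' @noRd
glszm_features <- function(M, np) {
  f <- rl_core(M, np)
  c(small_area_emphasis = f$short,
    large_area_emphasis = f$long,
    gray_level_nonuniformity = f$gln,
    gray_level_nonuniformity_normalized = f$glnn,
    size_zone_nonuniformity = f$sln,
    size_zone_nonuniformity_normalized = f$slnn,
    zone_percentage = f$pct,
    gray_level_variance = f$glv,
    zone_variance = f$sv,
    zone_entropy = f$entropy,
    low_gray_level_zone_emphasis = f$lowg,
    high_gray_level_zone_emphasis = f$highg,
    small_area_low_gray_level_emphasis = f$short_lowg)
}
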