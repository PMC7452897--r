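# First-order (histogram) statistics of ROI intensities.

#' Extract the 15 first-order statistics of ROI intensities
#'
#' Intensity statistics are computed on the raw ROI voxel values; the
#' histogram-based entries (`entropy`, Shannon entropy in bits, and
#' `uniformity`) use the equal-width discretisation of [discretize()] with
#' `n_bins` levels. For a constant ROI, skewness and kurtosis are defined as
#' 0 (with a warning) rather than NaN; kurtosis is the excess kurtosis, 0 for
#' a normal distribution.
#'
#' @param image A [volumetric_image].
#' @param mask An [roi_mask] on the same grid.
#' @param n_bins Gray levels for the histogram-based statistics.
#' @return Named numeric vector of length 15.
#' @export
extract_first_order <- function(image, mask, n_bins = 32L) {
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  assert_that(identical(dim(image$voxels), dim(mask$voxels)),
              "image and mask grids differ")
  x <- image$voxels[mask$voxels]
  n <- length(x)
  assert_that(n >= 1, "mask is empty")
  mu <- mean(x)
  v <- if (n > 1) sum((x - mu)^2) / n else 0  # population variance
  s <- sqrt(v)
  labels <- suppressWarnings(discretize(image, mask, n_bins))
  p <- tabulate(labels[mask$voxels], nbins = n_bins) / n
  p_nz <- p[p > 0]
  if (s > 0) {
    skew <- mean((x - mu)^3) / s^3
    kurt <- mean((x - mu)^4) / s^4 - 3
  } else {
    warning("constant ROI: skewness and kurtosis defined as 0")
    skew <- 0
    kurt <- 0
  }
  c(mean = mu,
    median = stats::median(x),
    minimum = min(x),
    maximum = max(x),
    range = max(x) - min(x),
    variance = v,
    standard_deviation = s,
    mean_absolute_deviation = mean(abs(x - mu)),
    root_mean_square = sqrt(mean(x^2)),
    energy = sum(x^2),
    entropy = -sum(p_nz * log2(p_nz)),
    uniformity = sum(p^2),
    skewness = skew,
    kurtosis = kurt,
    percentile_90 = unname(stats::quantile(x, 0.9, type = 7)))
}
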