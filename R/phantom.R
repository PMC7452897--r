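# Synthetic tumor phantoms: ellipsoidal ROIs carrying a correlated texture
# field whose amplitude is monotonically linked to a latent hazard, with
# T2W-like and two-b-value DWI channels (the DWI pair is consistent with a
# monoexponential decay through a spatially varying true ADC field).

#' Specify the phantom geometry and texture link
#'
#' @param grid_shape Integer length-3 grid size (voxels).
#' @param spacing_mm Voxel spacing (mm).
#' @param tumor_radius_range_mm `(lo, hi)` range the ellipsoid semi-axes are
#'   drawn from, `lo <= hi`.
#' @param heterogeneity_link `(intercept, slope)` mapping latent risk to the
#'   tumor texture-noise amplitude; `slope >= 0` so higher risk means rougher
#'   texture.
#' @param texture_correlation_length_mm Gaussian correlation length of the
#'   texture field (mm).
#' @param background_level Per-channel background: `t2w` in arbitrary
#'   intensity units, `adc` in 10^-3 mm^2/s.
#' @param tumor_contrast Per-channel additive tumor contrast (same units;
#'   negative ADC contrast emulates the restricted diffusion of tumor).
#' @param noise_sd Background white-noise level per channel.
#' @param adc_texture_scale Converts texture amplitude to ADC units.
#' @param s0_level DWI b=0 signal level (arbitrary units).
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L),
                         spacing_mm = c(2, 2, 2),
                         tumor_radius_range_mm = c(8, 14),
                         heterogeneity_link = c(intercept = 0.3, slope = 0.25),
                         texture_correlation_length_mm = 4,
                         background_level = c(t2w = 1.0, adc = 1.4),
                         tumor_contrast = c(t2w = 1.5, adc = -0.5),
                         noise_sd = c(t2w = 0.05, adc = 0.05),
                         adc_texture_scale = 0.15,
                         s0_level = 1000,
                         seed = 20260101L) {
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 4),
              "`grid_shape` must be 3 integers >= 4")
  assert_that(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "`spacing_mm` must be 3 positive reals")
  assert_that(length(tumor_radius_range_mm) == 2L &&
                tumor_radius_range_mm[1] <= tumor_radius_range_mm[2] &&
                tumor_radius_range_mm[1] > 0,
              "`tumor_radius_range_mm` must be (lo, hi) with 0 < lo <= hi")
  assert_that(heterogeneity_link[2] >= 0,
              "heterogeneity slope must be >= 0 (higher risk, rougher texture)")
  assert_that(texture_correlation_length_mm > 0,
              "`texture_correlation_length_mm` must be positive")
  extent <- grid_shape * spacing_mm
  assert_that(all(2 * tumor_radius_range_mm[2] <= extent - 2 * spacing_mm),
              "grid too small to contain the largest tumor")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
                 heterogeneity_link = as.numeric(heterogeneity_link),
                 texture_correlation_length_mm = texture_correlation_length_mm,
                 background_level = background_level,
                 tumor_contrast = tumor_contrast,
                 noise_sd = noise_sd,
                 adc_texture_scale = adc_texture_scale,
                 s0_level = s0_level,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Stationary Gaussian random field with unit variance
#'
#' White noise smoothed by a Gaussian kernel (circular convolution via FFT)
#' and rescaled to unit empirical variance. Draws from the current RNG state.
#' @noRd
gaussian_field <- function(dims, sigma_vox) {
  noise <- array(stats::rnorm(prod(dims)), dims)
  if (all(sigma_vox < 1e-8)) return(noise)
  kern1 <- function(n, s) {
    if (s < 1e-8) { k <- numeric(n); k[1] <- 1; return(k) }
    pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-pos^2 / (2 * s^2))
    k / sum(k)
  }
  k3 <- outer(outer(kern1(dims[1], sigma_vox[1]),
                    kern1(dims[2], sigma_vox[2])),
              kern1(dims[3], sigma_vox[3]))
  dim(k3) <- dims
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(k3), inverse = TRUE)) /
    prod(dims)
  sm / stats::sd(as.vector(sm))
}

#' Generate one phantom image pair plus mask
#'
#' Builds an ellipsoidal tumor (semi-axes drawn from the spec's radius range)
#' on the spec grid. Tumor voxels carry a stationary correlated Gaussian
#' texture field with amplitude `intercept + slope * latent_risk` (floored at
#' 0.02). Channels: a T2W-like volume; DWI b=0 and b=1000 volumes generated
#' from a true ADC field via `S(b) = S(0) exp(-b ADC)`, so [adc_from_dwi()]
#' recovers that field exactly. Deterministic given `seed`.
#'
#' @param spec A [phantom_spec].
#' @param latent_risk Scalar latent hazard driving texture heterogeneity.
#' @param seed RNG seed.
#' @return List with elements `t2w`, `dwi_b0`, `dwi_b1000`
#'   ([volumetric_image]s) and `mask` ([roi_mask]).
#' @export
generate_phantom_pair <- function(spec, latent_risk, seed) {
  assert_that(inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec")
  assert_that(is.finite(latent_risk), "`latent_risk` must be finite")
  with_seed(seed, {
    dims <- spec$grid_shape
    sp <- spec$spacing_mm
    semi <- stats::runif(3, spec$tumor_radius_range_mm[1],
                         spec$tumor_radius_range_mm[2])
    extent <- dims * sp
    assert_that(all(2 * semi <= extent - 2 * sp),
                "tumor does not fit the grid")
    centre <- extent / 2
    ax <- (seq_len(dims[1]) - 0.5) * sp[1]
    ay <- (seq_len(dims[2]) - 0.5) * sp[2]
    az <- (seq_len(dims[3]) - 0.5) * sp[3]
    dist2 <- outer(outer(((ax - centre[1]) / semi[1])^2,
                         ((ay - centre[2]) / semi[2])^2, `+`),
                   ((az - centre[3]) / semi[3])^2, `+`)
    inside <- dist2 <= 1
    assert_that(any(inside), "degenerate tumor (no voxels inside)")

    amp <- max(0.02, spec$heterogeneity_link[1] +
                 spec$heterogeneity_link[2] * latent_risk)
    sigma_vox <- spec$texture_correlation_length_mm / sp
    tex_t2w <- gaussian_field(dims, sigma_vox)
    tex_adc <- gaussian_field(dims, sigma_vox)

    t2w <- array(stats::rnorm(prod(dims), spec$background_level["t2w"],
                              spec$noise_sd["t2w"]), dims)
    t2w[inside] <- spec$background_level["t2w"] + spec$tumor_contrast["t2w"] +
      amp * tex_t2w[inside]

    adc <- array(stats::rnorm(prod(dims), spec$background_level["adc"],
                              spec$noise_sd["adc"]), dims)
    adc[inside] <- spec$background_level["adc"] + spec$tumor_contrast["adc"] +
      amp * spec$adc_texture_scale * tex_adc[inside]
    adc[adc < 0.05] <- 0.05  # keep diffusion physically positive

    b0 <- array(spec$s0_level, dims)
    b1000 <- b0 * exp(-adc)  # adc in 1e-3 mm^2/s, b = 1000 s/mm^2

    list(t2w = volumetric_image(t2w, sp, "T2W"),
         dwi_b0 = volumetric_image(b0, sp, "DWI_b0"),
         dwi_b1000 = volumetric_image(b1000, sp, "DWI_b1000"),
         mask = roi_mask(inside, sp))
  })
}

#' Randomly perturb an ROI boundary (synthetic second observer)
#'
#' Performs `magnitude` passes in which each 6-connected boundary voxel
#' (inner or outer) flips with probability 1/2, emulating inter-observer
#' delineation variability while preserving the interior core.
#'
#' @param mask An [roi_mask] with at least one voxel.
#' @param magnitude Maximum boundary displacement in voxels (integer >= 0).
#' @param seed RNG seed.
#' @return A perturbed, non-empty [roi_mask].
#' @export
perturb_mask <- function(mask, magnitude, seed) {
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  n <- sum(mask$voxels)
  assert_that(n >= 1, "mask is empty")
  r_eq <- (3 * n / (4 * pi))^(1 / 3)  # equivalent-sphere radius, voxels
  assert_that(magnitude < r_eq,
              "perturbation magnitude must be smaller than the tumor radius")
  if (magnitude == 0) return(mask)
  with_seed(seed, {
    m <- mask$voxels
    for (pass in seq_len(magnitude)) {
      nb <- neighbor_count6(m)
      inner <- m & nb < 6L          # inside, touching background
      outer <- !m & nb > 0L         # outside, touching foreground
      flip_in <- inner & array(stats::runif(length(m)) < 0.5, dim(m))
      flip_out <- outer & array(stats::runif(length(m)) < 0.5, dim(m))
      m2 <- m
      m2[flip_in] <- FALSE
      m2[flip_out] <- TRUE
      if (any(m2)) m <- m2
    }
    roi_mask(m, mask$spacing_mm)
  })
}

#' Count 6-connected foreground neighbours of every voxel
#' @noRd
neighbor_count6 <- function(m) {
  d <- dim(m)
  cnt <- array(0L, d)
  shift0 <- function(a, axis, by) {
    out <- array(FALSE, d)
    if (by == 1L) {
      switch(axis,
        out[-1, , ] <- a[-d[1], , , drop = FALSE],
        out[, -1, ] <- a[, -d[2], , drop = FALSE],
        out[, , -1] <- a[, , -d[3], drop = FALSE])
    } else {
      switch(axis,
        out[-d[1], , ] <- a[-1, , , drop = FALSE],
        out[, -d[2], ] <- a[, -1, , drop = FALSE],
        out[, , -d[3]] <- a[, , -1, drop = FALSE])
    }
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    cnt <- cnt + shift0(m, axis, by)
  cnt
}
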