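# Shared fixtures: small masks, images and survival tables built in code.

# digital ball mask of radius r_mm on an isotropic grid
ball_mask <- function(r_mm = 10, spacing = 1, pad = 2) {
  n <- ceiling(2 * (r_mm / spacing + pad))
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  roi_mask(d2 <= r_mm^2, spacing_mm = rep(spacing, 3))
}

cube_mask <- function(a_mm = 20, spacing = 1, pad = 2) {
  n <- a_mm / spacing + 2 * pad
  m <- array(FALSE, c(n, n, n))
  idx <- (pad + 1):(pad + a_mm / spacing)
  m[idx, idx, idx] <- TRUE
  roi_mask(m, spacing_mm = rep(spacing, 3))
}

# image with given voxel values inside a mask, noise elsewhere
image_on_mask <- function(mask, values, background = 0) {
  v <- array(background, dim(mask$voxels))
  v[mask$voxels] <- values
  volumetric_image(v, spacing_mm = mask$spacing_mm)
}

random_image <- function(dims = c(6, 6, 6), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volumetric_image(array(rnorm(prod(dims)), dims), spacing_mm = spacing)
}

full_mask <- function(dims = c(6, 6, 6), spacing = c(1, 1, 1)) {
  roi_mask(array(TRUE, dims), spacing_mm = spacing)
}

# simple survival record table
records_of <- function(time, event, ...) {
  data.frame(time_months = time, event = event, ...)
}

# exponential survival data with a binary covariate effect
sim_exp_records <- function(n, beta = 0, rate = 0.02, censor = 0,
                            admin = Inf, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate * exp(beta * x))
  t_c <- if (censor > 0) pmin(rexp(n, censor), admin) else rep(admin, n)
  data.frame(time_months = pmax(pmin(t_ev, t_c), 1e-9),
             event = as.integer(t_ev <= t_c), x = x)
}

# small phantom spec for fast tests
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), spacing_mm = c(2, 2, 2),
               tumor_radius_range_mm = c(6, 9), ...)
}

# small cohort model for fast tests
tiny_model <- function(...) {
  cohort_model(n_patients = c(primary = 40L, v1 = 30L, v2 = 30L, v3 = 30L),
               ...)
}
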