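# Shape and size features of the tumor ROI, in physical units.

#' Extract the 8 shape and size features of an ROI
#'
#' Volume is the voxel count times the voxel volume; surface area is the
#' total area of mask faces exposed to background (face-count method), so a
#' 20 mm cube mask has exactly `A = 6 a^2`. Derived descriptors:
#' * `sphericity = pi^(1/3) (6V)^(2/3) / A` (1 for a perfect sphere),
#' * `compactness_1 = V / (sqrt(pi) A^(3/2))`,
#' * `compactness_2 = 36 pi V^2 / A^3`,
#' * `spherical_disproportion = A / (4 pi r^2)` with equivalent-sphere radius
#'   `(3V / 4pi)^(1/3)`,
#' * `max_3d_diameter`: largest centre-to-centre distance between boundary
#'   voxels (mm).
#'
#' @param mask An [roi_mask] with at least one foreground voxel.
#' @return Named numeric vector of length 8.
#' @export
extract_shape <- function(mask) {
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  m <- mask$voxels
  sp <- mask$spacing_mm
  n <- sum(m)
  assert_that(n >= 1, "mask is empty")
  vox_vol <- prod(sp)
  volume <- n * vox_vol

  # exposed faces per axis: neighbour outside grid or background
  pad <- function(a, axis, front) {
    d <- dim(a)
    d[axis] <- 1L
    blank <- array(FALSE, d)
    if (front) switch(axis,
      abind3(blank, a[-dim(a)[1], , , drop = FALSE], 1L),
      abind3(blank, a[, -dim(a)[2], , drop = FALSE], 2L),
      abind3(blank, a[, , -dim(a)[3], drop = FALSE], 3L))
    else switch(axis,
      abind3(a[-1, , , drop = FALSE], blank, 1L),
      abind3(a[, -1, , drop = FALSE], blank, 2L),
      abind3(a[, , -1, drop = FALSE], blank, 3L))
  }
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  surface <- 0
  boundary <- array(FALSE, dim(m))
  for (axis in 1:3) {
    for (front in c(TRUE, FALSE)) {
      nb <- pad(m, axis, front)
      exposed <- m & !nb
      surface <- surface + sum(exposed) * face_area[axis]
      boundary <- boundary | exposed
    }
  }

  idx <- which(boundary, arr.ind = TRUE)
  coords <- sweep(idx, 2L, sp, `*`)
  if (nrow(coords) > 1L) {
    max_diam <- sqrt(max(as.vector(stats::dist(coords))^2))
  } else max_diam <- 0

  r_eq <- (3 * volume / (4 * pi))^(1 / 3)
  c(volume = volume,
    surface_area = surface,
    surface_to_volume_ratio = surface / volume,
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / surface,
    compactness_1 = volume / (sqrt(pi) * surface^1.5),
    compactness_2 = 36 * pi * volume^2 / surface^3,
    spherical_disproportion = surface / (4 * pi * r_eq^2),
    max_3d_diameter = max_diam)
}

#' Bind a slab onto a 3D array along an axis
#' @noRd
abind3 <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  d <- da; d[axis] <- da[axis] + db[axis]
  out <- array(vector(mode = typeof(a), 1L), d)
  ia <- lapply(seq_along(d), function(k) seq_len(da[k]))
  ib <- lapply(seq_along(d), function(k) seq_len(db[k]))
  ib[[axis]] <- da[axis] + ib[[axis]]
  out[ia[[1]], ia[[2]], ia[[3]]] <- a
  out[ib[[1]], ib[[2]], ib[[3]]] <- b
  out
}
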