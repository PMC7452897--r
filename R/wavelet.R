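# Single-level 3D stationary (undecimated) wavelet transform.
#
# Each axis is filtered with the quadrature pair of the chosen basis without
# downsampling (periodic boundary), so every sub-band lives on the original
# grid and the ROI mask applies unchanged. The eight L/H combinations are
# labelled by axis order: "LHH" = low-pass along x, high-pass along y and z.

#' Decompose a volume into 8 stationary wavelet sub-bands
#'
#' @param image A [volumetric_image].
#' @param wavelet Basis; currently `"haar"` (low-pass `(1,1)/sqrt(2)`,
#'   high-pass `(1,-1)/sqrt(2)`).
#' @return Named list of 8 [volumetric_image]s (`LLL` ... `HHH`), each on the
#'   input grid.
#' @export
wavelet_decompose <- function(image, wavelet = "haar") {
  assert_that(inherits(image, "volumetric_image"),
              "`image` must be a volumetric_image")
  assert_that(identical(wavelet, "haar"),
              "only the 'haar' basis is implemented")
  d <- dim(image$voxels)
  assert_that(all(d >= 2L), "volume dimensions must each be >= 2 (filter length)")
  x <- image$voxels
  filt <- function(a, axis, kind) {
    shifted <- circshift3d(a, axis, 1L)
    if (kind == "L") (a + shifted) / sqrt(2) else (a - shifted) / sqrt(2)
  }
  out <- list()
  for (cx in c("L", "H")) {
    ax_ <- filt(x, 1L, cx)
    for (cy in c("L", "H")) {
      axy <- filt(ax_, 2L, cy)
      for (cz in c("L", "H")) {
        sub <- filt(axy, 3L, cz)
        out[[paste0(cx, cy, cz)]] <-
          volumetric_image(sub, spacing_mm = image$spacing_mm,
                           modality = image$modality)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
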