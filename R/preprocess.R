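# Intensity preprocessing: ADC derivation, Z-score normalisation, gray-level
# discretisation, and feature-table I/O.

#' Derive an ADC map from a two-b-value DWI pair
#'
#' Fits the monoexponential decay model `S(b) = S(0) * exp(-b * ADC)` through
#' the two acquired b-values (0 and 1000 s/mm^2), i.e. per voxel
#' `ADC = ln(S_b0 / S_b1000) / 1000` in mm^2/s, reported in the conventional
#' units of 10^-3 mm^2/s. Voxels where either signal is non-positive cannot be
#' log-transformed; their ADC is set to 0 and their count reported in a
#' warning.
#'
#' @param b0 [volumetric_image] with modality `DWI_b0`.
#' @param b1000 [volumetric_image] with modality `DWI_b1000`, same grid.
#' @param b_value Diffusion weighting of the second acquisition (s/mm^2).
#' @return A [volumetric_image] with modality `ADC`, in 10^-3 mm^2/s.
#' @export
adc_from_dwi <- function(b0, b1000, b_value = 1000) {
  assert_that(inherits(b0, "volumetric_image") &&
                inherits(b1000, "volumetric_image"),
              "inputs must be volumetric_image objects")
  assert_that(identical(dim(b0$voxels), dim(b1000$voxels)),
              "b0 and b1000 grids differ")
  assert_that(max(abs(b0$spacing_mm - b1000$spacing_mm)) < 1e-6,
              "b0 and b1000 spacings differ")
  s0 <- b0$voxels
  s1 <- b1000$voxels
  bad <- s0 <= 0 | s1 <= 0
  adc <- array(0, dim(s0))
  ok <- !bad
  # ln ratio per voxel, scaled from mm^2/s to 1e-3 mm^2/s
  adc[ok] <- log(s0[ok] / s1[ok]) / b_value * 1000
  if (any(bad))
    warning(sprintf("%d voxel(s) with non-positive DWI signal mapped to ADC 0",
                    sum(bad)))
  volumetric_image(adc, spacing_mm = b0$spacing_mm, modality = "ADC")
}

#' Z-score normalise a volume
#'
#' Standardises the whole volume to mean 0 and standard deviation 1, applied
#' per patient and per sequence before feature extraction.
#'
#' @param image A [volumetric_image].
#' @return The normalised [volumetric_image].
#' @export
znormalize <- function(image) {
  assert_that(inherits(image, "volumetric_image"),
              "`image` must be a volumetric_image")
  v <- as.vector(image$voxels)
  s <- stats::sd(v)
  assert_that(s > 0, "cannot Z-normalise a constant volume (zero variance)")
  out <- (image$voxels - mean(v)) / s
  volumetric_image(out, spacing_mm = image$spacing_mm,
                   modality = image$modality)
}

#' Discretise ROI intensities into equal-width gray-level bins
#'
#' Bins span the ROI intensity range `[min, max]`; the maximum maps to bin
#' `n_bins`. Returns an integer array over the full grid with 0 outside the
#' ROI and labels in `1..n_bins` inside, the form the texture-matrix routines
#' consume.
#'
#' @param image A [volumetric_image].
#' @param mask An [roi_mask] on the same grid.
#' @param n_bins Number of gray levels (>= 2); default 32.
#' @return Integer 3D array of bin labels (0 = outside ROI).
#' @export
discretize <- function(image, mask, n_bins = 32L) {
  assert_that(inherits(image, "volumetric_image"), "`image` must be a volumetric_image")
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  assert_that(identical(dim(image$voxels), dim(mask$voxels)),
              "image and mask grids differ")
  assert_that(n_bins >= 2, "`n_bins` must be at least 2")
  inside <- mask$voxels
  assert_that(any(inside), "mask is empty")
  vals <- image$voxels[inside]
  lo <- min(vals); hi <- max(vals)
  labels <- array(0L, dim(image$voxels))
  if (hi == lo) {
    warning("constant ROI: all voxels assigned to bin 1")
    labels[inside] <- 1L
    return(labels)
  }
  bins <- floor((vals - lo) / (hi - lo) * n_bins) + 1L
  bins[bins > n_bins] <- as.integer(n_bins)  # max maps to n_bins
  labels[inside] <- as.integer(bins)
  labels
}

#' Write a feature table to delimited text
#'
#' Comma-separated with a header row; first column `patient_id`, remaining
#' columns fully qualified feature names (`sequence|group|subband|name`).
#'
#' @param table Data frame with a `patient_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  assert_that(is.data.frame(table), "`table` must be a data frame")
  assert_that("patient_id" %in% names(table),
              "feature table must have a patient_id column")
  assert_that(!anyDuplicated(table$patient_id),
              "duplicate patient_id in feature table")
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with `patient_id` as character and numeric features.
#' @export
read_feature_table <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = NA, stringsAsFactors = FALSE)
  assert_that("patient_id" %in% names(tab),
              "file has no patient_id column: not a feature table")
  assert_that(!anyDuplicated(tab$patient_id),
              "duplicate patient_id in feature table")
  tab$patient_id <- as.character(tab$patient_id)
  tab
}
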