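# Containers for 3D intensity volumes and binary ROI masks, plus NIfTI I/O.

#' Construct a volumetric image
#'
#' A `volumetric_image` is a 3D numeric array of intensities together with the
#' physical voxel spacing in millimetres and a modality tag. All downstream
#' feature computations take physical spacing into account.
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing_mm Numeric length-3 vector of positive voxel spacings (mm),
#'   in array axis order.
#' @param modality One of `"T2W"`, `"ADC"`, `"DWI_b0"`, `"DWI_b1000"`.
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(voxels, spacing_mm = c(1, 1, 1),
                             modality = c("T2W", "ADC", "DWI_b0", "DWI_b1000")) {
  modality <- match.arg(modality)
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "`voxels` must be a 3D array")
  assert_that(all(is.finite(voxels)), "intensities must all be finite")
  assert_that(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "`spacing_mm` must be 3 positive numbers")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 modality = modality),
            class = "volumetric_image")
}

#' Construct a binary ROI mask
#'
#' @param voxels 3D array coercible to logical (values in \{0, 1\}).
#' @param spacing_mm Voxel spacing in mm, matching the paired image.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing_mm = c(1, 1, 1)) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "`voxels` must be a 3D array")
  vals <- unique(as.vector(voxels))
  assert_that(all(vals %in% c(0, 1, TRUE, FALSE)),
              "mask voxels must be binary (0/1)")
  assert_that(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "`spacing_mm` must be 3 positive numbers")
  m <- array(as.logical(voxels), dim(voxels))
  structure(list(voxels = m, spacing_mm = as.numeric(spacing_mm)),
            class = "roi_mask")
}

#' @export
print.volumetric_image <- function(x, ...) {
  cat(sprintf("<volumetric_image %s: %s voxels, spacing %s mm>\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask: %s grid, %d foreground voxels>\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 3D image.
#' @param modality Modality tag to attach.
#' @return A [volumetric_image].
#' @export
load_volume <- function(path, modality = "T2W") {
  assert_that(file.exists(path), paste("no such file:", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3L,
              sprintf("expected a 3D volume, got %dD: %s", length(d), path))
  arr <- array(as.vector(img), d)  # plain array, NIfTI attributes dropped
  volumetric_image(arr, spacing_mm = RNifti::pixdim(img)[1:3],
                   modality = modality)
}

#' Read a binary ROI mask from a NIfTI file
#'
#' Voxels are binarised at 0.5; files holding label values other than 0/1 are
#' rejected rather than silently thresholded.
#'
#' @param path Path to a `.nii` / `.nii.gz` mask.
#' @param image Optional [volumetric_image]; if given, grid shape and spacing
#'   must match.
#' @return An [roi_mask].
#' @export
load_mask <- function(path, image = NULL) {
  assert_that(file.exists(path), paste("no such file:", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3L,
              sprintf("expected a 3D mask, got %dD: %s", length(d), path))
  arr <- array(as.vector(img), d)
  vals <- unique(as.vector(arr))
  assert_that(all(abs(vals) < 1e-6 | abs(vals - 1) < 1e-6),
              "mask file is not binary (values other than 0/1 present)")
  m <- roi_mask(array(arr > 0.5, dim(arr)),
                spacing_mm = RNifti::pixdim(img)[1:3])
  if (!is.null(image)) {
    assert_that(identical(dim(m$voxels), dim(image$voxels)),
                "mask grid does not match image grid")
    assert_that(max(abs(m$spacing_mm - image$spacing_mm)) < 1e-6,
                "mask spacing does not match image spacing")
  }
  m
}

#' Write a volume or mask to NIfTI
#'
#' @param x A [volumetric_image] or [roi_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "roi_mask")) array(as.numeric(x$voxels), dim(x$voxels))
         else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
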