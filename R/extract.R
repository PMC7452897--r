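# Per-sequence and per-patient feature extraction, and the ICC
# reproducibility screen.

#' Extract the 620-feature vector of one MR sequence
#'
#' Computes 8 shape + 15 first-order + 53 texture features on the original
#' (Z-normalised) image, then 15 first-order + 53 texture features on each of
#' the 8 stationary wavelet sub-bands — 620 features with qualified names
#' `group|subband|base_name` in catalog order. Deterministic: repeated calls
#' return bit-identical vectors.
#'
#' @param image A [volumetric_image] (normalise first with [znormalize()]).
#' @param mask An [roi_mask] on the same grid.
#' @param catalog Feature catalog from [feature_catalog()]; its `n_bins` and
#'   `wavelet` attributes parameterise the extraction.
#' @return Named numeric vector of length 620.
#' @export
extract_sequence <- function(image, mask, catalog = feature_catalog()) {
  n_bins <- attr(catalog, "n_bins") %||% 32L
  wav <- attr(catalog, "wavelet") %||% "haar"
  assert_that(identical(dim(image$voxels), dim(mask$voxels)),
              "image and mask grids differ")

  strip_tex <- function(v)
    stats::setNames(v, sub("^(glcm|glrlm|glszm)_", "\\1|", names(v)))
  qual <- function(v, subband) {
    nm <- names(v)
    has_grp <- grepl("|", nm, fixed = TRUE)
    nm <- ifelse(has_grp,
                 sub("|", paste0("|", subband, "|"), nm, fixed = TRUE),
                 paste("firstorder", subband, nm, sep = "|"))
    stats::setNames(v, nm)
  }

  shape_v <- extract_shape(mask)
  shape <- stats::setNames(shape_v,
                           paste("shape", "original", names(shape_v),
                                 sep = "|"))
  fo <- qual(extract_first_order(image, mask, n_bins), "original")
  tex <- qual(strip_tex(extract_texture(image, mask, n_bins)), "original")

  bands <- wavelet_decompose(image, wav)
  wav_feats <- lapply(names(bands), function(sb) {
    b <- bands[[sb]]
    c(qual(extract_first_order(b, mask, n_bins), sb),
      qual(strip_tex(extract_texture(b, mask, n_bins)), sb))
  })
  out <- c(shape, fo, tex, unlist(wav_feats))

  # align to catalog order and check cardinalities
  assert_that(setequal(names(out), catalog$name),
              "extracted names do not match the catalog")
  out <- out[catalog$name]
  counts <- feature_group_counts(names(out))
  stopifnot(counts["shape"] == 8L, counts["firstorder"] == 15L,
            counts["texture"] == 53L, counts["wavelet"] == 544L,
            length(out) == 620L, all(is.finite(out)))
  out
}

#' Extract the 1240-feature vector of one patient
#'
#' Concatenates the 620 T2W-sequence features and the 620 ADC-sequence
#' features with sequence-qualified names (`T2W|...`, `ADC|...`). Both
#' sequences are required; there is no imputation for a missing one.
#'
#' @param t2w,adc Z-normalised [volumetric_image]s of the two sequences.
#' @param mask_t2w,mask_adc [roi_mask]s aligned to each sequence.
#' @param catalog Feature catalog.
#' @return Named numeric vector of length 1240.
#' @export
extract_patient <- function(t2w, adc, mask_t2w, mask_adc,
                            catalog = feature_catalog()) {
  assert_that(!is.null(t2w) && !is.null(adc),
              "both T2W and ADC sequences are required (no imputation)")
  f_t2w <- extract_sequence(t2w, mask_t2w, catalog)
  f_adc <- extract_sequence(adc, mask_adc, catalog)
  out <- c(stats::setNames(f_t2w, paste0("T2W|", names(f_t2w))),
           stats::setNames(f_adc, paste0("ADC|", names(f_adc))))
  stopifnot(length(out) == 1240L, !anyDuplicated(names(out)))
  out
}

#' Inter-observer reproducibility screen via ICC
#'
#' Computes, per feature, the two-way random-effects absolute-agreement
#' single-measurement intraclass correlation ICC(2,1) between two raters'
#' feature tables (e.g. features extracted from two independent tumor
#' delineations), and retains features with ICC above the threshold.
#'
#' With mean squares from the two-way ANOVA (n subjects, k = 2 raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Features with zero between-subject variance get ICC 0 with a warning.
#'
#' @param table_a,table_b Feature tables (data frames with `patient_id`) from
#'   the two raters; same patients, same features.
#' @param threshold Retention threshold (default 0.6).
#' @return List with `icc` (named numeric) and `retained` (character vector
#'   of feature names with ICC > threshold).
#' @export
compute_feature_icc <- function(table_a, table_b, threshold = 0.6) {
  assert_that(setequal(table_a$patient_id, table_b$patient_id),
              "the two tables must cover the same patients")
  feats <- setdiff(names(table_a), "patient_id")
  assert_that(setequal(feats, setdiff(names(table_b), "patient_id")),
              "the two tables must have the same features")
  table_b <- table_b[match(table_a$patient_id, table_b$patient_id), ]
  n <- nrow(table_a)
  assert_that(n >= 3, "ICC needs at least 3 patients")
  k <- 2
  degenerate <- 0L
  icc <- vapply(feats, function(f) {
    x <- cbind(table_a[[f]], table_b[[f]])
    row_m <- rowMeans(x)
    col_m <- colMeans(x)
    grand <- mean(x)
    msr <- k * sum((row_m - grand)^2) / (n - 1)
    msc <- n * sum((col_m - grand)^2) / (k - 1)
    sse <- sum((x - outer(row_m, rep(1, k)) -
                  outer(rep(1, n), col_m) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    denom <- msr + (k - 1) * mse + k / n * (msc - mse)
    if (denom <= 0 || (msr - mse) == 0 && denom == 0) return(NA_real_)
    val <- (msr - mse) / denom
    if (!is.finite(val)) NA_real_ else val
  }, 0)
  bad <- !is.finite(icc)
  if (any(bad)) {
    warning(sprintf("%d feature(s) with zero between-subject variance: ICC set to 0",
                    sum(bad)))
    icc[bad] <- 0
  }
  list(icc = icc, retained = feats[icc > threshold])
}
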