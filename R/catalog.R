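# The canonical radiomic feature catalog: names, groups and cardinalities.
#
# The per-sequence feature set has four groups — 8 shape, 15 first-order,
# 53 texture (24 GLCM + 16 GLRLM + 13 GLSZM) and 544 wavelet features
# (8 undecimated sub-bands x (15 first-order + 53 texture)) — 620 features
# per sequence and 1240 per patient over the T2W and ADC sequences. The
# individual definitions follow the IBSI reference nomenclature.

.shape_names <- c(
  "volume", "surface_area", "surface_to_volume_ratio", "sphericity",
  "compactness_1", "compactness_2", "spherical_disproportion",
  "max_3d_diameter")

.firstorder_names <- c(
  "mean", "median", "minimum", "maximum", "range", "variance",
  "standard_deviation", "mean_absolute_deviation", "root_mean_square",
  "energy", "entropy", "uniformity", "skewness", "kurtosis", "percentile_90")

.glcm_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "inverse_difference", "inverse_difference_moment",
  "idmn", "idn", "inverse_variance", "maximum_probability", "sum_average",
  "sum_entropy", "sum_variance", "dissimilarity", "imc1", "imc2")

.glrlm_names <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
  "run_length_nonuniformity_normalized", "run_percentage",
  "gray_level_variance", "run_variance", "run_entropy",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis")

.glszm_names <- c(
  "small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
  "size_zone_nonuniformity_normalized", "zone_percentage",
  "gray_level_variance", "zone_variance", "zone_entropy",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_area_low_gray_level_emphasis")

.subband_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' The radiomic feature catalog
#'
#' Enumerates, in stable order, every feature the extractor produces for one
#' MR sequence: 8 shape, 15 first-order and 53 texture features on the
#' original image, plus the 15 first-order and 53 texture features on each of
#' the 8 single-level undecimated wavelet sub-bands (544 wavelet features) —
#' 620 in total. Qualified names have the form `group|subband|name`;
#' [extract_patient()] prefixes the sequence (`T2W|...`, `ADC|...`).
#'
#' @param n_bins Gray-level count used by histogram-based features (recorded
#'   as a catalog parameter).
#' @param wavelet Wavelet basis identifier (currently `"haar"`).
#' @return A data frame with columns `name` (qualified), `group`, `subband`,
#'   `base_name`, and attributes `n_bins`, `wavelet`.
#' @export
feature_catalog <- function(n_bins = 32L, wavelet = "haar") {
  orig <- data.frame(
    group = c(rep("shape", 8L), rep("firstorder", 15L), rep("glcm", 24L),
              rep("glrlm", 16L), rep("glszm", 13L)),
    subband = "original",
    base_name = c(.shape_names, .firstorder_names, .glcm_names,
                  .glrlm_names, .glszm_names),
    stringsAsFactors = FALSE)
  wav <- do.call(rbind, lapply(.subband_names, function(sb) {
    data.frame(
      group = c(rep("firstorder", 15L), rep("glcm", 24L), rep("glrlm", 16L),
                rep("glszm", 13L)),
      subband = sb,
      base_name = c(.firstorder_names, .glcm_names, .glrlm_names,
                    .glszm_names),
      stringsAsFactors = FALSE)
  }))
  cat_df <- rbind(orig, wav)
  cat_df$name <- paste(cat_df$group, cat_df$subband, cat_df$base_name,
                       sep = "|")
  cat_df <- cat_df[, c("name", "group", "subband", "base_name")]
  stopifnot(nrow(cat_df) == 620L, !anyDuplicated(cat_df$name))
  attr(cat_df, "n_bins") <- as.integer(n_bins)
  attr(cat_df, "wavelet") <- wavelet
  cat_df
}

#' Count catalog features by group
#'
#' Tallies a vector of qualified feature names into the four reported groups:
#' shape, first-order, texture (GLCM + GLRLM + GLSZM on the original image)
#' and wavelet (everything computed on a sub-band).
#'
#' @param names Character vector of qualified names (`group|subband|name`,
#'   optionally sequence-prefixed).
#' @return Named integer vector with entries `shape`, `firstorder`,
#'   `texture`, `wavelet`.
#' @export
feature_group_counts <- function(names) {
  parts <- strsplit(names, "|", fixed = TRUE)
  # strip an optional sequence prefix
  parts <- lapply(parts, function(p) if (length(p) == 4L) p[-1L] else p)
  grp <- vapply(parts, `[`, "", 1L)
  sb <- vapply(parts, `[`, "", 2L)
  c(shape = sum(grp == "shape"),
    firstorder = sum(grp == "firstorder" & sb == "original"),
    texture = sum(grp %in% c("glcm", "glrlm", "glszm") & sb == "original"),
    wavelet = sum(sb != "original"))
}
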