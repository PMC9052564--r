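# Feature catalogue: the fixed enumeration of the 1150 extracted features.
# 16 shape features (mask only) + 9 channels (original + 8 wavelet) x
# (48 intensity + 78 texture) = 1150. Feature names are
# "<channel>_<family>_<feature>" with the shape block on the original
# channel. The exact published per-feature list is not available; this
# enumeration is a consistent IBSI-style reconstruction around the published
# total and the five signature features.

intensity_feature_names <- function() {
  base <- c("mean", "variance", "skewness", "kurtosis", "median", "minimum",
            "p10", "p90", "maximum", "iqr", "range", "mad", "rmad", "medad",
            "cov", "qcod")
  c(paste0("stat_", c(base, "energy", "rms")),
    paste0("ih_", c(base, "mode", "entropy", "uniformity", "max_grad",
                    "max_grad_level", "min_grad", "min_grad_level")),
    paste0("ivh_", c("v10", "v90", "i10", "i90", "v10_minus_v90",
                     "i10_minus_i90", "auc")))
}

texture_feature_names <- function() {
  glcm <- c("joint_max", "joint_avg", "joint_var", "joint_entropy",
            "diff_avg", "diff_var", "diff_entropy", "sum_avg", "sum_var",
            "sum_entropy", "energy", "contrast", "dissimilarity", "inv_diff",
            "inv_diff_norm", "inv_diff_mom", "inv_diff_mom_norm", "inv_var",
            "correlation", "autocorrelation", "cluster_tendency",
            "cluster_shade", "cluster_prominence", "info_corr1", "info_corr2")
  c(paste0("glcm_", glcm),
    paste0("glrlm_", rl_feature_names("glrlm")),
    paste0("glszm_", rl_feature_names("glszm")),
    paste0("gldzm_", rl_feature_names("gldzm")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")))
}

shape_feature_names <- function() {
  paste0("shape_", c("volume", "surface_area", "sv_ratio", "compactness1",
                     "compactness2", "spherical_disproportion", "sphericity",
                     "asphericity", "max_diameter", "major_axis",
                     "minor_axis", "least_axis", "elongation", "flatness",
                     "vol_density_aabb", "area_density_aabb"))
}

wavelet_channels <- function() {
  c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
}

#' The default radiomic feature catalogue
#'
#' Enumerates all 1150 features: 16 shape descriptors from the mask, plus 48
#' intensity and 78 texture features on each of the 9 image channels (the
#' original CT and the 8 undecimated coiflet-1 wavelet channels). Column
#' names are `<channel>_<family>_<feature>`; the shape block is attached to
#' the `original` channel.
#'
#' @return data.frame with columns `name`, `channel`, `family`, `feature`.
#' @export
feature_catalogue <- function() {
  per_channel <- c(intensity_feature_names(), texture_feature_names())
  chans <- c("original", wavelet_channels())
  rows <- list(data.frame(
    name = paste0("original_", shape_feature_names()),
    channel = "original", family = "shape",
    feature = shape_feature_names(), stringsAsFactors = FALSE))
  for (ch in chans) {
    fam <- sub("_.*$", "", per_channel)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(ch, "_", per_channel), channel = ch, family = fam,
      feature = per_channel, stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(cat$name))
  cat
}

#' Extraction configuration
#'
#' @param bank wavelet filter bank, default [coif1_bank()].
#' @param scheme_original discretisation for the calibrated-HU original
#'   channel (default fixed bin size 25 HU anchored at -1000 HU).
#' @param scheme_wavelet discretisation for wavelet channels, whose
#'   intensities are not HU-calibrated (default 64 fixed bins).
#' @param aggregation direction aggregation for GLCM/GLRLM: `"merged"`
#'   (single matrix over the 13 directions, default) or `"averaged"`.
#' @param clip optional `c(low, high)` HU re-segmentation window applied to
#'   the original-channel ROI intensities before discretisation (none by
#'   default).
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(bank = coif1_bank(),
                              scheme_original = discretisation_scheme("fbs", bin_width = 25, anchor = -1000),
                              scheme_wavelet = discretisation_scheme("fbn", n_bins = 64L),
                              aggregation = c("merged", "averaged"),
                              clip = NULL) {
  structure(list(bank = bank, scheme_original = scheme_original,
                 scheme_wavelet = scheme_wavelet,
                 aggregation = match.arg(aggregation), clip = clip),
            class = "extraction_config")
}
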