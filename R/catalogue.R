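#' The fixed radiomic feature catalogue
#'
#' The pipeline ships a fixed catalogue of 35 features: 19 first-order
#' (intensity histogram) features and 16 gray-level size zone matrix
#' (GLSZM) texture features. The order is fixed and deterministic; it
#' defines the layout of every feature vector the pipeline assembles.
#'
#' @return a list with character vectors `first_order` (19 names),
#'   `glszm` (16 names) and `all` (their concatenation, 35 names).
#' @export
#' @examples
#' length(feature_catalogue()$all) # 35
feature_catalogue <- function() {
  first_order <- c(
    "fo_energy", "fo_total_energy", "fo_entropy", "fo_minimum",
    "fo_p10", "fo_p90", "fo_maximum", "fo_mean", "fo_median",
    "fo_interquartile_range", "fo_range", "fo_mad", "fo_rmad",
    "fo_rms", "fo_sd", "fo_skewness", "fo_kurtosis", "fo_variance",
    "fo_uniformity"
  )
  glszm <- c(
    "szm_small_area_emphasis", "szm_large_area_emphasis",
    "szm_gray_level_nonuniformity", "szm_gray_level_nonuniformity_norm",
    "szm_size_zone_nonuniformity", "szm_size_zone_nonuniformity_norm",
    "szm_zone_percentage", "szm_gray_level_variance", "szm_zone_variance",
    "szm_zone_entropy", "szm_low_gray_level_zone_emphasis",
    "szm_high_gray_level_zone_emphasis",
    "szm_small_area_low_gray_level_emphasis",
    "szm_small_area_high_gray_level_emphasis",
    "szm_large_area_low_gray_level_emphasis",
    "szm_large_area_high_gray_level_emphasis"
  )
  list(first_order = first_order, glszm = glszm,
       all = c(first_order, glszm))
}
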