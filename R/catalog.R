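#' The 99-feature catalogue
#'
#' The full feature set computed per scan, in report order: 37
#' first-order features (decay-corrected ROI statistics, LoG entropies,
#' volume descriptors and SUV statistics), 25 second-order (GLCM and
#' grey-level difference matrix), 31 high-order (run-length, size-zone
#' and neighbourhood grey-tone difference) and 6 fractal features.
#'
#' @return A tibble with columns `feature` (snake_case name) and
#'   `family` (`"first"`, `"second"`, `"high"`, `"fractal"`).
#' @examples
#' table(feature_catalog()$family)
#' @export
feature_catalog <- function() {
  first <- c(
    "roi_mean", "roi_maximum", "roi_minimum", "roi_range",
    "roi_standard_deviation", "roi_skewness", "roi_kurtosis",
    "roi_coefficient_of_variation", "roi_median",
    "roi_10th_percentile", "roi_25th_percentile",
    "roi_75th_percentile", "roi_90th_percentile",
    "roi_entropy", "roi_energy",
    "roi_log_entropy_1_5", "roi_log_entropy_2_0", "roi_log_entropy_2_5",
    "metabolic_active_volume_cm3", "effective_diameter_cm",
    "suv_mean", "suv_total_lesion_glycolysis", "suv_peak",
    "suv_maximum", "suv_minimum", "suv_range", "suv_standard_deviation",
    "suv_skewness", "suv_kurtosis", "suv_coefficient_of_variation",
    "suv_median", "suv_10th_percentile", "suv_25th_percentile",
    "suv_75th_percentile", "suv_90th_percentile",
    "suv_entropy", "suv_energy"
  )
  second <- c(
    "glcm_autocorrelation", "glcm_cluster_prominence", "glcm_cluster_shade",
    "glcm_contrast", "glcm_correlation", "glcm_difference_entropy",
    "glcm_difference_variance", "glcm_dissimilarity", "glcm_energy",
    "glcm_entropy", "glcm_homogeneity",
    "glcm_information_measure_correlation_1",
    "glcm_information_measure_correlation_2",
    "glcm_inverse_difference_moment",
    "glcm_inverse_difference_moment_normalised",
    "glcm_inverse_difference_normalised",
    "glcm_maximum_probability", "glcm_sum_average", "glcm_sum_entropy",
    "glcm_sum_of_squares_variance", "glcm_sum_variance",
    "gldm_mean", "gldm_entropy", "gldm_variance", "gldm_contrast"
  )
  high <- c(
    "glrl_short_run_emphasis", "glrl_long_run_emphasis",
    "glrl_grey_level_nonuniformity", "glrl_run_length_nonuniformity",
    "glrl_run_percentage", "glrl_low_grey_level_run_emphasis",
    "glrl_high_grey_level_run_emphasis",
    "glrl_short_run_low_grey_level_emphasis",
    "glrl_short_run_high_grey_level_emphasis",
    "glrl_long_run_low_grey_level_emphasis",
    "glrl_long_run_high_grey_level_emphasis",
    "glrl_intensity_variability", "glrl_run_length_variability",
    "glszm_short_zone_emphasis", "glszm_long_zone_emphasis",
    "glszm_intensity_nonuniformity", "glszm_zone_length_nonuniformity",
    "glszm_zone_percentage", "glszm_low_intensity_zone_emphasis",
    "glszm_high_intensity_zone_emphasis",
    "glszm_short_zone_low_intensity_emphasis",
    "glszm_short_zone_high_intensity_emphasis",
    "glszm_long_zone_low_intensity_emphasis",
    "glszm_long_zone_high_intensity_emphasis",
    "glszm_intensity_variability", "glszm_size_zone_variability",
    "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
    "ngtdm_complexity", "ngtdm_texture_strength"
  )
  fractal <- c(
    "fd_mean", "fd_sd", "fd_lacunarity", "fd_hurst_exponent",
    "fd_blanket_mean", "fd_inverse"
  )
  tibble::tibble(
    feature = c(first, second, high, fractal),
    family = rep(c("first", "second", "high", "fractal"),
                 c(length(first), length(second), length(high),
                   length(fractal)))
  )
}

#' Family sizes of the feature catalogue
#' @return Named integer vector `c(first = 37, second = 25, high = 31, fractal = 6)`.
#' @export
feature_family_sizes <- function() {
  fc <- feature_catalog()
  tab <- table(factor(fc$family, levels = c("first", "second", "high", "fractal")))
  stats::setNames(as.integer(tab), names(tab))
}
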