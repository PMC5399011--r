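#' Pipeline configuration
#'
#' All tunable analysis settings with defaults matching the clinical
#' protocol emulated by the package: 64 grey-level bins, LoG scales
#' 1.5/2.0/2.5 mm, 7 directions x 2 distances for the pairwise texture
#' matrices, 26-connected zones and neighbourhoods, an 8-voxel fractal
#' window with box ladder {2, 4, 8}, and the F-18 half-life.
#'
#' @param n_bins grey-level bins for quantization.
#' @param log_sigmas_mm LoG filter scales, mm.
#' @param directions integer matrix of 3D directions (rows).
#' @param distances distance multipliers for GLCM/GLDM offsets.
#' @param fractal_window_vox fractal window edge, voxels.
#' @param fractal_box_sizes DBC/lacunarity box ladder.
#' @param blanket_dilations blanket iterations.
#' @param hurst_lags variogram lags, voxels.
#' @param half_life_min isotope half-life, minutes.
#' @param suv_peak_radius_mm radius of the 1 cm^3 SUV-peak sphere.
#' @param alpha significance level for the paired comparison.
#' @param wilcoxon_exact_max largest n for the exact Wilcoxon branch.
#' @param wilcoxon_zeros zero-difference handling, `"discard"` or
#'   `"pratt"`.
#' @return A `petex_config` list.
#' @export
petex_config <- function(n_bins = 64,
                         log_sigmas_mm = c(1.5, 2.0, 2.5),
                         directions = default_directions(),
                         distances = c(1L, 2L),
                         fractal_window_vox = 8,
                         fractal_box_sizes = c(2, 4, 8),
                         blanket_dilations = 5,
                         hurst_lags = 4,
                         half_life_min = 109.77,
                         suv_peak_radius_mm = 6.2,
                         alpha = 0.05,
                         wilcoxon_exact_max = 25,
                         wilcoxon_zeros = "discard") {
  stopifnot(n_bins >= 2, all(log_sigmas_mm > 0), all(distances >= 1))
  structure(as.list(environment()), class = "petex_config")
}
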