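#' Extract the 99-feature vector from one scan
#'
#' Runs the full per-scan pipeline: decay correction of the raw VOI
#' intensities to injection time, first-order statistics, 64-bin
#' histogram entropy/energy, LoG-response entropies, volume
#' descriptors, SUV conversion and SUV statistics, directionally
#' averaged matrix features on the quantized VOI, and the six fractal
#' features. Degenerate features are carried as `NA` (with names
#' recorded in the `flags` attribute), never dropped, so the output
#' always has the full 99-name catalogue.
#'
#' @param pet a [scalar_volume()] with units `ACTIVITY_BQ_ML` (or
#'   `ARBITRARY`, in which case SUV features require `meta` and assume
#'   Bq/ml).
#' @param mask a [voi_mask()]; mapped onto the PET grid if not already
#'   congruent.
#' @param meta an [acquisition_meta()].
#' @param config a [petex_config()].
#' @return A one-row tibble with 99 feature columns in catalogue order,
#'   with a `flags` attribute.
#' @export
extract_features <- function(pet, mask, meta, config = petex_config()) {
  stopifnot(inherits(pet, "scalar_volume"), inherits(mask, "voi_mask"),
            inherits(meta, "acquisition_meta"),
            inherits(config, "petex_config"))
  mask <- map_mask_to_grid(mask, pet)
  flags <- character(0)

  # decay-corrected "ROI" intensity volume
  dc <- decay_factor(meta$uptake_time_min, meta$half_life_min)
  roi_vol <- scalar_volume(pet$data * dc, pet$spacing, pet$origin,
                           "ARBITRARY")
  voi <- extract_voi(roi_vol, mask)
  st <- firstorder_stats(voi$values)
  flags <- c(flags, attr(st, "flags"))
  he <- histogram_entropy_energy(quantize(voi$values, config$n_bins))
  le <- log_entropies(roi_vol, mask, config$log_sigmas_mm, config$n_bins)
  vf <- volume_features(mask)

  suv_vol <- to_suv(scalar_volume(pet$data, pet$spacing, pet$origin,
                                  "ACTIVITY_BQ_ML"), meta)
  sf <- suv_features(suv_vol, mask, config$n_bins)
  flags <- c(flags, paste0("suv_", attr(sf, "flags")))

  q <- quantize_voi(roi_vol, mask, config$n_bins)
  mf <- matrix_features(q, config$directions, config$distances)
  flags <- c(flags, attr(mf, "flags"))

  ff <- tryCatch(
    fractal_features(roi_vol, mask, config$fractal_window_vox,
                     config$fractal_box_sizes, config$blanket_dilations,
                     config$hurst_lags),
    error = function(e) {
      flags <<- c(flags, paste0("fractal_failed: ", conditionMessage(e)))
      setNames(rep(NA_real_, 6),
               c("fd_mean", "fd_sd", "fd_lacunarity", "fd_hurst_exponent",
                 "fd_blanket_mean", "fd_inverse"))
    })

  vals <- c(
    roi_mean = st[["mean"]], roi_maximum = st[["max"]],
    roi_minimum = st[["min"]], roi_range = st[["range"]],
    roi_standard_deviation = st[["sd"]], roi_skewness = st[["skewness"]],
    roi_kurtosis = st[["kurtosis"]],
    roi_coefficient_of_variation = st[["cv"]],
    roi_median = st[["median"]],
    roi_10th_percentile = st[["p10"]], roi_25th_percentile = st[["p25"]],
    roi_75th_percentile = st[["p75"]], roi_90th_percentile = st[["p90"]],
    roi_entropy = he[["entropy"]], roi_energy = he[["energy"]],
    roi_log_entropy_1_5 = le[[1]], roi_log_entropy_2_0 = le[[2]],
    roi_log_entropy_2_5 = le[[3]],
    metabolic_active_volume_cm3 = vf[["mav_cm3"]],
    effective_diameter_cm = vf[["effective_diameter_cm"]],
    suv_mean = sf[["mean"]], suv_total_lesion_glycolysis = sf[["tlg"]],
    suv_peak = sf[["peak"]], suv_maximum = sf[["max"]],
    suv_minimum = sf[["min"]], suv_range = sf[["range"]],
    suv_standard_deviation = sf[["sd"]], suv_skewness = sf[["skewness"]],
    suv_kurtosis = sf[["kurtosis"]],
    suv_coefficient_of_variation = sf[["cv"]],
    suv_median = sf[["median"]], suv_10th_percentile = sf[["p10"]],
    suv_25th_percentile = sf[["p25"]], suv_75th_percentile = sf[["p75"]],
    suv_90th_percentile = sf[["p90"]],
    suv_entropy = sf[["entropy"]], suv_energy = sf[["energy"]]
  )
  vals <- c(vals, mf, ff)
  cat_names <- feature_catalog()$feature
  stopifnot(setequal(names(vals), cat_names))
  out <- tibble::as_tibble(as.list(vals[cat_names]))
  attr(out, "flags") <- unique(flags)
  out
}

resolve_scan <- function(tp) {
  pet <- tp$pet
  msk <- tp$mask
  if (is.character(pet)) pet <- read_volume(pet, units = "ACTIVITY_BQ_ML")
  if (pet$units == "ARBITRARY") pet$units <- "ACTIVITY_BQ_ML"
  if (is.character(msk)) msk <- read_mask(msk)
  meta <- tp$meta
  if (!inherits(meta, "acquisition_meta")) meta <- do.call(acquisition_meta, meta)
  list(pet = pet, mask = msk, meta = meta)
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to the early and late scan of every
#' study. Studies whose scans fail to load or process are skipped with
#' a warning naming the patient, and the pipeline continues.
#'
#' @param studies a `phantom_cohort`, a list of `study_manifest`s (with
#'   file paths), or a list of in-memory studies as produced by
#'   [generate_cohort()].
#' @param config a [petex_config()].
#' @return Tibble with columns `patient_id`, `group`, `timepoint`
#'   (`"early"`/`"late"`) and the 99 feature columns.
#' @export
extract_cohort_features <- function(studies, config = petex_config()) {
  if (inherits(studies, "phantom_cohort")) studies <- studies$studies
  rows <- list()
  for (s in studies) {
    res <- tryCatch({
      e <- resolve_scan(s$early)
      l <- resolve_scan(s$late)
      fe <- extract_features(e$pet, e$mask, e$meta, config)
      fl <- extract_features(l$pet, l$mask, l$meta, config)
      dplyr::bind_rows(
        dplyr::bind_cols(tibble::tibble(patient_id = s$patient_id,
                                        group = s$group,
                                        timepoint = "early"), fe),
        dplyr::bind_cols(tibble::tibble(patient_id = s$patient_id,
                                        group = s$group,
                                        timepoint = "late"), fl))
    }, error = function(err) {
      warning("skipping patient ", s$patient_id, ": ",
              conditionMessage(err), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("extract_cohort_features: no usable studies",
                              call. = FALSE)
  dplyr::bind_rows(rows)
}

#' Run a full paired study end to end
#'
#' Cohort feature extraction followed by the paired early-versus-late
#' comparison, optionally writing the report bundle (feature CSV,
#' comparison CSV, family summary CSV, markdown report and the resolved
#' configuration) to `out_dir`.
#'
#' @inheritParams extract_cohort_features
#' @param out_dir optional output directory.
#' @return A list with `features` (tibble) and `comparison` (a
#'   `timepoint_comparison`).
#' @export
run_study <- function(studies, config = petex_config(), out_dir = NULL) {
  features <- extract_cohort_features(studies, config)
  comparison <- compare_timepoints(features, alpha = config$alpha,
                                   exact_max = config$wilcoxon_exact_max,
                                   zeros = config$wilcoxon_zeros)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    readr::write_csv(tidy(comparison), file.path(out_dir, "comparison.csv"))
    readr::write_csv(summarize_families(comparison),
                     file.path(out_dir, "family_summary.csv"))
    write_markdown_report(comparison, file.path(out_dir, "report.md"))
    writeLines(config_text(config), file.path(out_dir, "config.txt"))
  }
  list(features = features, comparison = comparison)
}

config_text <- function(config) {
  vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.matrix(v)) v <- paste(apply(v, 1, paste, collapse = ","),
                                 collapse = "; ")
    paste0(k, " = ", paste(v, collapse = ", "))
  }, character(1))
}
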