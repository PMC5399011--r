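#' Specification of a synthetic paired-phantom cohort
#'
#' Defines the study conditions emulated by the generator: a cohort of
#' patients with ellipsoidal tumours on the clinical PET grid
#' (4.7 x 4.7 x 3.27 mm voxels), scanned at two post-injection time
#' points (~101.5 and ~251.7 min). Tumour uptake is heterogeneous
#' (lognormal modulation by a correlated Gaussian field); between the
#' scans, benign lesions wash out by a multiplicative factor `w < 1` on
#' the SUV scale while malignant lesions intensify their hottest decile
#' of voxels by a factor `g > 1`. Gaussian noise with variance
#' proportional to local activity times the decay factor makes later
#' (count-poorer) scans noisier, and both scans are post-filtered with
#' a 6 mm FWHM Gaussian.
#'
#' @param n_patients cohort size (default 54).
#' @param benign_fraction fraction of benign lesions (default 30/54).
#' @param grid_shape integer 3-vector of volume dimensions.
#' @param spacing_mm voxel spacing, mm.
#' @param semi_axes_range_mm range of ellipsoid semi-axes, mm.
#' @param base_suv mean tumour SUV before modulation.
#' @param background_suv background SUV outside the tumour.
#' @param dispersion lognormal sigma of the heterogeneity field.
#' @param correlation_length_mm texture correlation length, mm.
#' @param washout benign washout factor `w` (late = w * early, SUV scale).
#' @param focal_gain malignant gain `g` applied to the hottest decile.
#' @param noise_kappa noise scale: activity-space variance is
#'   `kappa * local_activity * decay_factor(t)`; 0 disables noise.
#' @param early_time_min,late_time_min post-injection scan times, min.
#' @param smoothing_fwhm_mm reconstruction post-filter FWHM, mm.
#' @param injected_activity_mbq,body_weight_kg acquisition defaults.
#' @param half_life_min F-18 half-life, min.
#' @param seed master seed; every generated cohort is a deterministic
#'   function of (spec, seed).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_patients = 54,
                         benign_fraction = 30 / 54,
                         grid_shape = c(24, 24, 32),
                         spacing_mm = c(4.7, 4.7, 3.27),
                         semi_axes_range_mm = c(10, 26),
                         base_suv = 1.4,
                         background_suv = 0.3,
                         dispersion = 0.3,
                         correlation_length_mm = 10,
                         washout = 0.8,
                         focal_gain = 1.5,
                         noise_kappa = 2,
                         early_time_min = 101.5,
                         late_time_min = 251.7,
                         smoothing_fwhm_mm = 6,
                         injected_activity_mbq = 350,
                         body_weight_kg = 70,
                         half_life_min = 109.77,
                         seed = 1L) {
  stopifnot(n_patients >= 1, benign_fraction > 0, benign_fraction < 1,
            washout > 0, washout <= 1, focal_gain >= 1,
            early_time_min > 0, late_time_min > 0, noise_kappa >= 0,
            length(grid_shape) == 3, all(grid_shape >= 4),
            semi_axes_range_mm[1] <= semi_axes_range_mm[2])
  structure(as.list(environment()), class = "phantom_spec")
}

#' Zero-mean unit-variance correlated Gaussian field
#'
#' Smooths white noise with a Gaussian of sigma equal to the requested
#' correlation length and renormalises to unit variance, giving a
#' stationary random field whose autocorrelation scale is set by
#' `correlation_length_mm`.
#'
#' @param shape integer 3-vector.
#' @param correlation_length_mm correlation length, mm (> 0).
#' @param spacing_mm voxel spacing, mm.
#' @param seed integer seed (optional; uses the current RNG state when
#'   `NULL`).
#' @return 3D numeric array with (sample) mean 0 and variance 1.
#' @export
generate_correlated_field <- function(shape, correlation_length_mm,
                                      spacing_mm, seed = NULL) {
  stopifnot(correlation_length_mm > 0)
  if (!is.null(seed)) set.seed(seed)
  wn <- array(rnorm(prod(shape)), dim = shape)
  sig_vox <- correlation_length_mm / spacing_mm
  ks <- lapply(sig_vox, gaussian_kernel_1d)
  sm <- separable_filter(wn, ks)
  sm <- sm - mean(sm)
  s <- sqrt(mean(sm^2))
  if (s == 0) return(sm)
  sm / s
}

ellipsoid_mask <- function(grid_shape, spacing_mm, semi_axes_mm) {
  centre <- (grid_shape - 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - 1 - centre[a]) *
                                   spacing_mm[a] / semi_axes_mm[a])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  (r2 <= 1) * 1L
}

# one patient's paired scans, on the SUV scale before activity scaling
simulate_patient_fields <- function(spec, group) {
  semi <- runif(3, spec$semi_axes_range_mm[1], spec$semi_axes_range_mm[2])
  if (any(2 * semi > (spec$grid_shape - 2) * spec$spacing_mm)) {
    stop("phantom: tumour larger than grid", call. = FALSE)
  }
  msk <- ellipsoid_mask(spec$grid_shape, spec$spacing_mm, semi)
  fld <- generate_correlated_field(spec$grid_shape,
                                   spec$correlation_length_mm,
                                   spec$spacing_mm, seed = NULL)
  uptake <- spec$base_suv * exp(spec$dispersion * fld -
                                  spec$dispersion^2 / 2)
  early <- array(spec$background_suv, spec$grid_shape)
  early[msk == 1L] <- uptake[msk == 1L]
  late <- early
  if (group == "benign") {
    late[msk == 1L] <- spec$washout * early[msk == 1L]
  } else if (group == "malignant") {
    vals <- early[msk == 1L]
    thr <- quantile(vals, 0.9, names = FALSE)
    hot <- msk == 1L & early >= thr
    late[hot] <- spec$focal_gain * late[hot]
  }
  list(mask = msk, early = early, late = late)
}

suv_to_activity <- function(suv_arr, spec, t_min) {
  a_decayed_bq <- spec$injected_activity_mbq * 1e6 /
    decay_factor(t_min, spec$half_life_min)
  suv_arr * a_decayed_bq / (spec$body_weight_kg * 1000)
}

apply_noise_and_smoothing <- function(act, spec, t_min) {
  if (spec$noise_kappa > 0) {
    sdv <- sqrt(spec$noise_kappa * pmax(act, 0) *
                  decay_factor(t_min, spec$half_life_min))
    act <- act + array(rnorm(length(act)), dim(act)) * sdv
  }
  v <- scalar_volume(act, spec$spacing_mm, units = "ARBITRARY")
  if (spec$smoothing_fwhm_mm > 0) {
    v <- gaussian_fwhm_filter(v, spec$smoothing_fwhm_mm)
  }
  scalar_volume(pmax(v$data, 0), spec$spacing_mm, units = "ACTIVITY_BQ_ML")
}

#' Generate a synthetic paired cohort
#'
#' Draws `n_patients` studies under a [phantom_spec()]. When `out_dir`
#' is `NULL` the studies are returned in memory (each with
#' `scalar_volume` scans and a `voi_mask`); otherwise NIfTI volumes and
#' masks, a JSON manifest and a ground-truth CSV are written to disk
#' and the manifest references the files.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir optional output directory.
#' @return A `phantom_cohort` list with `studies` (per-patient scans or
#'   a manifest of paths), `ground_truth` (tibble) and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n_benign <- round(spec$n_patients * spec$benign_fraction)
  groups <- rep(c("benign", "malignant"),
                c(n_benign, spec$n_patients - n_benign))
  studies <- vector("list", spec$n_patients)
  gt <- vector("list", spec$n_patients)
  meta_e <- acquisition_meta(spec$injected_activity_mbq, spec$body_weight_kg,
                             uptake_time_min = spec$early_time_min,
                             half_life_min = spec$half_life_min)
  meta_l <- acquisition_meta(spec$injected_activity_mbq, spec$body_weight_kg,
                             uptake_time_min = spec$late_time_min,
                             half_life_min = spec$half_life_min)
  for (p in seq_len(spec$n_patients)) {
    f <- simulate_patient_fields(spec, groups[p])
    act_e <- suv_to_activity(f$early, spec, spec$early_time_min)
    act_l <- suv_to_activity(f$late, spec, spec$late_time_min)
    vol_e <- apply_noise_and_smoothing(act_e, spec, spec$early_time_min)
    vol_l <- apply_noise_and_smoothing(act_l, spec, spec$late_time_min)
    msk <- voi_mask(f$mask, spec$spacing_mm)
    pid <- sprintf("P%03d", p)
    studies[[p]] <- list(patient_id = pid, group = groups[p],
                         early = list(pet = vol_e, mask = msk, meta = meta_e),
                         late = list(pet = vol_l, mask = msk, meta = meta_l))
    inm <- f$mask == 1L
    gt[[p]] <- tibble::tibble(
      patient_id = pid, group = groups[p],
      true_early_mean_suv = mean(f$early[inm]),
      true_late_mean_suv = mean(f$late[inm]),
      washout = if (groups[p] == "benign") spec$washout else 1,
      focal_gain = if (groups[p] == "malignant") spec$focal_gain else 1,
      n_tumour_voxels = sum(inm))
  }
  ground_truth <- dplyr::bind_rows(gt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- lapply(studies, function(s) {
      paths <- list(
        pet_e = file.path(out_dir, paste0(s$patient_id, "_early.nii.gz")),
        msk_e = file.path(out_dir, paste0(s$patient_id, "_mask_early.nii.gz")),
        pet_l = file.path(out_dir, paste0(s$patient_id, "_late.nii.gz")),
        msk_l = file.path(out_dir, paste0(s$patient_id, "_mask_late.nii.gz")))
      write_volume(s$early$pet, paths$pet_e)
      write_volume(s$early$mask, paths$msk_e)
      write_volume(s$late$pet, paths$pet_l)
      write_volume(s$late$mask, paths$msk_l)
      study_manifest(s$patient_id, s$group,
                     early = list(pet = paths$pet_e, mask = paths$msk_e,
                                  meta = unclass(s$early$meta)),
                     late = list(pet = paths$pet_l, mask = paths$msk_l,
                                 meta = unclass(s$late$meta)))
    })
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))
    studies <- manifest
  }
  structure(list(studies = studies, ground_truth = ground_truth, spec = spec),
            class = "phantom_cohort")
}
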