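#' Acquisition metadata for SUV and decay correction
#'
#' Holds the quantities needed to convert an activity-concentration
#' volume (Bq/ml) to body-weight SUV and to decay-correct measured
#' values back to injection time. Times may be given either directly as
#' the uptake time in minutes, or as injection/scan timestamps (any
#' representation `difftime` understands: `POSIXct`, or parseable
#' date-time strings).
#'
#' @param injected_activity_mbq injected activity in MBq at injection
#'   time (adult protocol 350 MBq +/- 10%).
#' @param body_weight_kg body weight in kg.
#' @param uptake_time_min minutes from injection to scan start. If
#'   `NULL`, computed from `injection_time` and `scan_time`.
#' @param injection_time,scan_time optional timestamps.
#' @param half_life_min isotope half-life in minutes (F-18: 109.77).
#' @return An `acquisition_meta` list.
#' @examples
#' acquisition_meta(350, 70, uptake_time_min = 101.5)
#' @export
acquisition_meta <- function(injected_activity_mbq, body_weight_kg,
                             uptake_time_min = NULL,
                             injection_time = NULL, scan_time = NULL,
                             half_life_min = 109.77) {
  if (is.null(uptake_time_min)) {
    if (is.null(injection_time) || is.null(scan_time)) {
      stop("acquisition_meta: need uptake_time_min or both timestamps",
           call. = FALSE)
    }
    uptake_time_min <- as.numeric(difftime(as.POSIXct(scan_time),
                                           as.POSIXct(injection_time),
                                           units = "mins"))
  }
  stopifnot(is.finite(injected_activity_mbq), injected_activity_mbq > 0,
            is.finite(body_weight_kg), body_weight_kg > 0,
            is.finite(half_life_min), half_life_min > 0)
  if (uptake_time_min < 0) {
    stop("acquisition_meta: scan time precedes injection time", call. = FALSE)
  }
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 body_weight_kg = body_weight_kg,
                 uptake_time_min = uptake_time_min,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Radioactive decay correction factor
#'
#' Factor `2^(delta_t / half_life)` referring a value measured
#' `delta_t` minutes after injection back to injection time.
#'
#' @param delta_t_min elapsed minutes since injection (>= 0).
#' @param half_life_min isotope half-life in minutes.
#' @return Positive scalar (vectorised over `delta_t_min`).
#' @examples
#' decay_factor(109.77, 109.77) # one half-life -> 2
#' @export
decay_factor <- function(delta_t_min, half_life_min = 109.77) {
  stopifnot(is.finite(half_life_min), half_life_min > 0)
  if (any(delta_t_min < 0)) {
    stop("decay_factor: negative elapsed time", call. = FALSE)
  }
  2^(delta_t_min / half_life_min)
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUV(v) = c(v) / (A_decayed / W)` with the injected activity decayed
#' to scan time (`A_decayed = A * 1e6 / 2^(dt/T_half)` Bq) and
#' `W = body_weight * 1000` g, assuming tissue density 1 g/ml.
#'
#' @param volume a [scalar_volume()] with units `ACTIVITY_BQ_ML`.
#' @param meta an [acquisition_meta()].
#' @return A [scalar_volume()] with units `SUV`.
#' @export
to_suv <- function(volume, meta) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(meta, "acquisition_meta"))
  if (volume$units != "ACTIVITY_BQ_ML") {
    stop("to_suv: volume units must be ACTIVITY_BQ_ML, got ", volume$units,
         call. = FALSE)
  }
  a_decayed_bq <- meta$injected_activity_mbq * 1e6 /
    decay_factor(meta$uptake_time_min, meta$half_life_min)
  w_g <- meta$body_weight_kg * 1000
  scalar_volume(volume$data / (a_decayed_bq / w_g),
                spacing = volume$spacing, origin = volume$origin,
                units = "SUV")
}

#' Extract VOI voxel values
#'
#' Returns the values of foreground voxels in stable lexicographic
#' index order (first axis fastest), together with their voxel indices.
#'
#' @param volume a [scalar_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @return List with `values` (numeric) and `index` (n x 3 integer
#'   matrix of 1-based voxel indices).
#' @export
extract_voi <- function(volume, mask) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(mask, "voi_mask"))
  if (!same_grid(volume, mask)) {
    stop("extract_voi: mask grid is not congruent with the volume grid",
         call. = FALSE)
  }
  fg <- which(mask$data != 0L)
  if (length(fg) == 0L) stop("extract_voi: empty mask", call. = FALSE)
  list(values = as.numeric(volume$data[fg]),
       index = arrayInd(fg, dim(mask$data)))
}

#' Quantize intensities into equally spaced bins
#'
#' Resamples intensities to `n_bins` discrete equally spaced bins over
#' the observed `[min, max]` range:
#' `bin(v) = 1 + floor(n_bins * (v - vmin) / (vmax - vmin))`, with
#' `v = vmax` clamped into bin `n_bins`. A degenerate constant input
#' maps every value to bin 1.
#'
#' @param values non-empty numeric vector.
#' @param n_bins number of bins (>= 2), default 64.
#' @return List with `bin` (integer vector), `edges` (length
#'   `n_bins + 1` bin boundaries) and `n_bins`.
#' @examples
#' quantize(c(0, 0.5, 1), n_bins = 2)$bin # 1 2 2
#' @export
quantize <- function(values, n_bins = 64) {
  stopifnot(length(values) > 0, n_bins >= 2, all(is.finite(values)))
  vmin <- min(values); vmax <- max(values)
  if (vmax <= vmin) {
    return(list(bin = rep(1L, length(values)),
                edges = vmin + seq(0, 1, length.out = n_bins + 1),
                n_bins = as.integer(n_bins)))
  }
  b <- 1L + as.integer(floor(n_bins * (values - vmin) / (vmax - vmin)))
  b[b > n_bins] <- as.integer(n_bins)
  list(bin = b,
       edges = seq(vmin, vmax, length.out = n_bins + 1),
       n_bins = as.integer(n_bins))
}

#' Quantized VOI on its spatial grid
#'
#' Applies [quantize()] to the VOI voxels of a volume and arranges the
#' bin indices in the VOI bounding box, with 0 marking voxels outside
#' the VOI. This is the input to all matrix-based texture features.
#'
#' @inheritParams extract_voi
#' @param n_bins number of grey-level bins, default 64.
#' @return A `quantized_voi` list: `bin_array` (3D integer array over
#'   the bounding box, 0 = outside VOI), `values` (raw VOI values),
#'   `bin` (per-voxel bins, same order as `values`), `edges`, `n_bins`,
#'   `spacing`, `n_voxels`.
#' @export
quantize_voi <- function(volume, mask, n_bins = 64) {
  voi <- extract_voi(volume, mask)
  q <- quantize(voi$values, n_bins)
  rng <- apply(voi$index, 2, range)
  dims <- rng[2, ] - rng[1, ] + 1L
  arr <- array(0L, dims)
  arr[cbind(voi$index[, 1] - rng[1, 1] + 1L,
            voi$index[, 2] - rng[1, 2] + 1L,
            voi$index[, 3] - rng[1, 3] + 1L)] <- q$bin
  structure(list(bin_array = arr, values = voi$values, bin = q$bin,
                 edges = q$edges, n_bins = q$n_bins,
                 spacing = volume$spacing, n_voxels = length(voi$values)),
            class = "quantized_voi")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# second derivative of a Gaussian, sampled; corrected to zero DC response
gaussian_d2_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(2L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- g * (x^2 - sigma_vox^2) / sigma_vox^4
  k - mean(k)
}

separable_filter <- function(arr, kernels) {
  for (a in 1:3) {
    arr <- conv_axis_mirror(arr, kernels[[a]], a - 1L)
  }
  arr
}

#' Gaussian smoothing with FWHM given in millimetres
#'
#' Separable Gaussian filter with per-axis sigma
#' `(fwhm_mm / 2.3548) / spacing_axis` (anisotropy-aware) and mirror
#' boundary handling, so a constant volume is exactly preserved and the
#' total sum is conserved up to numerical precision.
#'
#' @param volume a [scalar_volume()].
#' @param fwhm_mm full-width at half maximum in mm (> 0).
#' @return Smoothed [scalar_volume()] with unchanged units.
#' @export
gaussian_fwhm_filter <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "scalar_volume"), fwhm_mm > 0)
  sig <- fwhm_to_sigma(fwhm_mm) / volume$spacing
  ks <- lapply(sig, gaussian_kernel_1d)
  out <- separable_filter(volume$data, ks)
  scalar_volume(out, volume$spacing, volume$origin, volume$units)
}

#' 3D Laplacian-of-Gaussian filter
#'
#' Band-pass response `LoG = d2/dx2 + d2/dy2 + d2/dz2` of the Gaussian-
#' smoothed volume, computed separably with per-axis sigma
#' `sigma_mm / spacing_axis` voxels and derivatives taken per mm, with
#' mirror boundaries. The response to a constant volume is exactly zero
#' (the derivative kernels have zero DC gain).
#'
#' @param volume a [scalar_volume()].
#' @param sigma_mm Gaussian standard deviation in mm (> 0); must be at
#'   least 0.1 voxel on every axis.
#' @return Filtered [scalar_volume()] with units `ARBITRARY`.
#' @export
log_filter <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "scalar_volume"), sigma_mm > 0)
  sig_vox <- sigma_mm / volume$spacing
  if (any(sig_vox < 0.1)) {
    stop("log_filter: sigma below 0.1 voxel on some axis (unstable kernel)",
         call. = FALSE)
  }
  out <- array(0, dim(volume$data))
  for (d_axis in 1:3) {
    ks <- lapply(1:3, function(a) {
      if (a == d_axis) {
        # derivative w.r.t. physical mm: kernel in voxel units / spacing^2
        gaussian_d2_kernel_1d(sig_vox[a]) / volume$spacing[a]^2
      } else {
        gaussian_kernel_1d(sig_vox[a])
      }
    })
    out <- out + separable_filter(volume$data, ks)
  }
  scalar_volume(out, volume$spacing, volume$origin, "ARBITRARY")
}
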