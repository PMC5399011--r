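#' First-order intensity statistics
#'
#' Thirteen summary statistics of a value list: mean, max, min, range,
#' population standard deviation (divisor N), skewness `m3 / m2^1.5`,
#' non-excess kurtosis `m4 / m2^2` (a Gaussian gives 3), coefficient of
#' variation `sd / mean`, median and the 10th/25th/75th/90th
#' percentiles (linear interpolation between order statistics).
#'
#' Degenerate inputs are flagged rather than erroring: zero variance
#' returns skewness and kurtosis 0, and a zero mean with positive sd
#' returns `NaN` for the coefficient of variation. Flags are attached
#' as a `flags` attribute.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric vector of length 13 with a `flags` attribute
#'   (character vector, possibly empty).
#' @examples
#' firstorder_stats(c(1, 2, 3, 4))[["sd"]] # population sd 1.118
#' @export
firstorder_stats <- function(values) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  flags <- character(0)
  if (m2 <= 0) {
    skew <- 0; kurt <- 0
    flags <- c(flags, "zero_variance")
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  }
  s <- sqrt(m2)
  if (mu == 0 && s > 0) {
    cv <- NaN
    flags <- c(flags, "cv_undefined")
  } else if (mu == 0) {
    cv <- 0
  } else {
    cv <- s / mu
  }
  qs <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  out <- c(mean = mu, max = max(values), min = min(values),
           range = max(values) - min(values), sd = s,
           skewness = skew, kurtosis = kurt, cv = cv,
           median = median(values),
           p10 = qs[1], p25 = qs[2], p75 = qs[3], p90 = qs[4])
  attr(out, "flags") <- flags
  out
}

#' Histogram entropy and energy of a quantized VOI
#'
#' With bin occupancy fractions `p_i`, entropy is `-sum p_i log2 p_i`
#' (bits, so at most `log2(n_bins)`) and energy (uniformity) is
#' `sum p_i^2`.
#'
#' @param q result of [quantize()] or [quantize_voi()].
#' @return Named numeric vector `c(entropy, energy)`.
#' @export
histogram_entropy_energy <- function(q) {
  p <- tabulate(q$bin, nbins = q$n_bins) / length(q$bin)
  p <- p[p > 0]
  c(entropy = -sum(p * log2(p)), energy = sum(p^2))
}

#' Entropies of Laplacian-of-Gaussian responses
#'
#' For each scale sigma (mm): filter the full volume with [log_filter()],
#' extract the VOI voxels of the response, re-quantize them to `n_bins`
#' equally spaced bins, and take the histogram entropy. The filter runs
#' on the whole volume (not the masked region) to avoid edge artefacts
#' at the VOI boundary.
#'
#' @inheritParams extract_voi
#' @param sigmas_mm numeric vector of LoG scales in mm.
#' @param n_bins number of bins for the response histogram.
#' @return Named numeric vector `log_entropy_<sigma>` (one per scale,
#'   with `.` replaced by `_` in the name).
#' @export
log_entropies <- function(volume, mask, sigmas_mm = c(1.5, 2.0, 2.5),
                          n_bins = 64) {
  out <- vapply(sigmas_mm, function(s) {
    f <- log_filter(volume, s)
    v <- extract_voi(f, mask)$values
    histogram_entropy_energy(quantize(v, n_bins))[["entropy"]]
  }, numeric(1))
  names(out) <- paste0("log_entropy_", gsub("\\.", "_", format(sigmas_mm,
                                                               nsmall = 1)))
  names(out) <- gsub(" ", "", names(out))
  out
}

#' Metabolic active volume and effective diameter
#'
#' `mav_cm3` is the foreground voxel count times the voxel volume
#' (cm^3); `effective_diameter_cm` is the diameter of the sphere of
#' equal volume, `(6 * mav / pi)^(1/3)`.
#'
#' @param mask a non-empty [voi_mask()].
#' @return Named numeric vector `c(mav_cm3, effective_diameter_cm)`.
#' @export
volume_features <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  n <- n_foreground(mask)
  if (n == 0L) stop("volume_features: empty mask", call. = FALSE)
  mav <- n * prod(mask$spacing) / 1000
  c(mav_cm3 = mav, effective_diameter_cm = effective_diameter(mav))
}

#' @rdname volume_features
#' @param mav_cm3 metabolic active volume in cm^3.
#' @export
effective_diameter <- function(mav_cm3) {
  (6 * mav_cm3 / pi)^(1 / 3)
}

#' SUV-derived first-order features
#'
#' The 17 SUV features: the 13 statistics of [firstorder_stats()] on
#' the SUV values, histogram entropy and energy of the 64-bin quantized
#' SUV values, total lesion glycolysis `TLG = SUV_mean * MAV`, and
#' `SUV_peak` - the maximum over foreground voxels of the mean SUV in a
#' 1 cm^3 sphere (radius 6.2 mm) centred on the voxel, the sphere
#' clipped to the VOI.
#'
#' @param suv_volume a [scalar_volume()] with units `SUV`.
#' @param mask the tumour [voi_mask()] on the same grid.
#' @param n_bins histogram bins for entropy/energy.
#' @return Named numeric vector of 17 values with a `flags` attribute.
#' @export
suv_features <- function(suv_volume, mask, n_bins = 64) {
  stopifnot(suv_volume$units == "SUV")
  voi <- extract_voi(suv_volume, mask)
  st <- firstorder_stats(voi$values)
  he <- histogram_entropy_energy(quantize(voi$values, n_bins))
  vf <- volume_features(mask)
  out <- c(mean = st[["mean"]], tlg = st[["mean"]] * vf[["mav_cm3"]],
           peak = suv_peak(suv_volume, mask, voi),
           max = st[["max"]], min = st[["min"]], range = st[["range"]],
           sd = st[["sd"]], skewness = st[["skewness"]],
           kurtosis = st[["kurtosis"]], cv = st[["cv"]],
           median = st[["median"]], p10 = st[["p10"]], p25 = st[["p25"]],
           p75 = st[["p75"]], p90 = st[["p90"]],
           entropy = he[["entropy"]], energy = he[["energy"]])
  attr(out, "flags") <- attr(st, "flags")
  out
}

# voxel offsets whose centres lie within radius_mm of the centre voxel
sphere_offsets <- function(spacing, radius_mm = 6.2) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d <- sqrt((g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2)
  as.matrix(g[d <= radius_mm, , drop = FALSE])
}

suv_peak <- function(suv_volume, mask, voi = NULL, radius_mm = 6.2) {
  off <- sphere_offsets(suv_volume$spacing, radius_mm)
  dm <- dim(suv_volume$data)
  fg <- mask$data != 0L
  vals <- suv_volume$data * fg
  acc_sum <- array(0, dm)
  acc_n <- array(0, dm)
  # accumulate, per centre voxel, the sum and count of in-VOI sphere
  # members via shifted-array addition (sphere clipped to grid and VOI)
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    src <- lapply(1:3, function(a) {
      s <- seq_len(dm[a]) + o[a]
      s[s >= 1 & s <= dm[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] - o[a])
    acc_sum[dst[[1]], dst[[2]], dst[[3]]] <-
      acc_sum[dst[[1]], dst[[2]], dst[[3]]] +
      vals[src[[1]], src[[2]], src[[3]]]
    acc_n[dst[[1]], dst[[2]], dst[[3]]] <-
      acc_n[dst[[1]], dst[[2]], dst[[3]]] +
      fg[src[[1]], src[[2]], src[[3]]]
  }
  ok <- fg & acc_n > 0
  max(acc_sum[ok] / acc_n[ok])
}
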