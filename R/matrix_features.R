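#' Default 3D direction set
#'
#' The seven-direction reduction of the 13 unique 3D neighbour
#' directions: the three axes, three face diagonals and one body
#' diagonal. Offsets are formed as `distance * direction`.
#'
#' @return A 7 x 3 integer matrix, one direction per row.
#' @export
default_directions <- function() {
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, 0, 1,
           1, 1, 0,
           1, 0, 1,
           0, 1, 1,
           1, 1, 1), ncol = 3, byrow = TRUE)
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Grey-level co-occurrence matrix for one offset
#'
#' Counts, over ordered in-VOI voxel pairs `(v, v + offset)`, the joint
#' occurrences of bin pairs; each pair increments both `(a, b)` and
#' `(b, a)`, so the matrix is symmetric by construction. Normalised
#' probabilities sum to 1.
#'
#' @param q a [quantize_voi()] result.
#' @param offset integer 3-vector (non-zero), in voxels.
#' @return List with `counts`, `p` (normalised matrix), `n_pairs`, and
#'   `empty` (TRUE when the VOI admits no pair along the offset).
#' @export
build_glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_voi"), any(offset != 0))
  counts <- cpp_glcm(q$bin_array, as.integer(offset), q$n_bins)
  tot <- sum(counts)
  list(counts = counts,
       p = if (tot > 0) counts / tot else counts,
       n_pairs = tot / 2,
       empty = tot == 0)
}

#' @rdname build_glcm
#' @export
build_gldm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_voi"), any(offset != 0))
  h <- cpp_gldm(q$bin_array, as.integer(offset), q$n_bins)
  tot <- sum(h)
  list(counts = h, p = if (tot > 0) h / tot else h,
       n_pairs = tot, empty = tot == 0)
}

#' @rdname build_glcm
#' @param direction integer 3-vector; runs are maximal same-bin voxel
#'   sequences along it (step 1), terminated by VOI gaps.
#' @export
build_glrlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_voi"), any(direction != 0))
  m <- cpp_glrlm(q$bin_array, as.integer(direction), q$n_bins)
  list(counts = m, n_runs = sum(m), empty = sum(m) == 0)
}

#' @rdname build_glcm
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  zones <- cpp_glszm_zones(q$bin_array)
  max_size <- if (nrow(zones) > 0) max(zones[, 2]) else 1L
  m <- matrix(0, q$n_bins, max_size)
  for (r in seq_len(nrow(zones))) {
    m[zones[r, 1], zones[r, 2]] <- m[zones[r, 1], zones[r, 2]] + 1
  }
  list(counts = m, n_zones = nrow(zones), empty = nrow(zones) == 0)
}

#' @rdname build_glcm
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  tab <- cpp_ngtdm(q$bin_array, q$n_bins)
  nv <- sum(tab[, 1])
  list(n_i = tab[, 1], s_i = tab[, 2], n_valid = nv, empty = nv == 0)
}

#' Haralick and extended co-occurrence features
#'
#' The 21 GLCM features on a normalised symmetric co-occurrence matrix.
#' Logs are base 2 with the `0 log 0 = 0` convention. `homogeneity` and
#' `inverse difference moment` both use the `1/(1 + (i-j)^2)` weight;
#' `difference variance` is the second moment `sum d^2 p_d` of the
#' absolute-difference distribution, so it coincides with `contrast`.
#' A zero-variance marginal returns `correlation = 0` with a
#' degeneracy flag.
#'
#' @param g result of [build_glcm()].
#' @return Named numeric vector of 21 values (prefixed `glcm_`), with a
#'   `flags` attribute.
#' @export
glcm_features <- function(g) {
  p <- g$p
  nb <- nrow(p)
  flags <- character(0)
  # work on the nonzero cells only; the matrix is sparse for small VOIs
  nz <- which(p > 0)
  pv <- p[nz]
  iv <- (nz - 1L) %% nb + 1L
  jv <- (nz - 1L) %/% nb + 1L
  dv <- abs(iv - jv)
  px <- as.numeric(rowsum(c(pv, numeric(nb)),
                          c(iv, seq_len(nb))))  # row marginal, all nb levels
  mu <- sum(seq_len(nb) * px)
  sig2 <- sum((seq_len(nb) - mu)^2 * px)
  p_diff <- rowsum(pv, dv)                      # occupied differences only
  d_occ <- as.numeric(rownames(p_diff))
  p_sum <- rowsum(pv, iv + jv)
  k_occ <- as.numeric(rownames(p_sum))

  contrast <- sum(dv^2 * pv)
  if (sig2 > 1e-12) {
    correlation <- (sum(iv * jv * pv) - mu^2) / sig2
  } else {
    correlation <- 0
    flags <- c(flags, "glcm_zero_marginal_variance")
  }
  hxy <- -sum(pv * log2(pv))
  # entropies of the marginal-product distribution: since sum(px) = 1,
  # HXY1 reduces to a sum over nonzero cells and HXY2 to 2 * HX
  lpx <- log2(px[px > 0])
  hx <- -sum(px[px > 0] * lpx)
  llook <- rep(NA_real_, nb); llook[px > 0] <- lpx
  hxy1 <- -sum(pv * (llook[iv] + llook[jv]))
  hxy2 <- 2 * hx
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else {
    flags <- c(flags, "glcm_imc1_degenerate"); 0
  }
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  sum_avg <- sum(k_occ * p_sum)

  out <- c(
    autocorrelation = sum(iv * jv * pv),
    cluster_prominence = sum((iv + jv - 2 * mu)^4 * pv),
    cluster_shade = sum((iv + jv - 2 * mu)^3 * pv),
    contrast = contrast,
    correlation = correlation,
    difference_entropy = -sum(p_diff * log2(p_diff)),
    difference_variance = sum(d_occ^2 * p_diff),
    dissimilarity = sum(dv * pv),
    energy = sum(pv^2),
    entropy = hxy,
    homogeneity = sum(pv / (1 + dv^2)),
    information_measure_correlation_1 = imc1,
    information_measure_correlation_2 = imc2,
    inverse_difference_moment = sum(pv / (1 + dv^2)),
    inverse_difference_moment_normalised = sum(pv / (1 + dv^2 / nb^2)),
    inverse_difference_normalised = sum(pv / (1 + dv / nb)),
    maximum_probability = max(pv),
    sum_average = sum_avg,
    sum_entropy = -sum(p_sum * log2(p_sum)),
    sum_of_squares_variance = sum((iv - mu)^2 * pv),
    sum_variance = sum((k_occ - sum_avg)^2 * p_sum)
  )
  names(out) <- paste0("glcm_", names(out))
  attr(out, "flags") <- flags
  out
}

#' Grey-level difference features
#'
#' Mean, entropy (bits), variance and contrast of the absolute
#' bin-difference histogram at one offset. By construction
#' `gldm_mean == glcm_dissimilarity` and
#' `gldm_contrast == glcm_contrast` for the same offset.
#'
#' @param g result of [build_gldm()].
#' @return Named numeric vector of 4 values (prefixed `gldm_`).
#' @export
gldm_features <- function(g) {
  p <- g$p
  d <- seq_along(p) - 1
  m <- sum(d * p)
  out <- c(mean = m,
           entropy = -sum(xlog2(p)),
           variance = sum((d - m)^2 * p),
           contrast = sum(d^2 * p))
  names(out) <- paste0("gldm_", names(out))
  out
}

#' Run-length features
#'
#' The 13 run-length features (Galloway/Chu conventions) plus the
#' intensity- and run-length-variability statistics, defined as the
#' population variance of the marginal run counts over grey levels
#' (all `n_bins` levels) and over run lengths (1 to the longest
#' observed run) respectively.
#'
#' @param g result of [build_glrlm()].
#' @param n_voxels number of VOI voxels (for run percentage).
#' @return Named numeric vector of 13 values (prefixed `glrl_`).
#' @export
glrlm_features <- function(g, n_voxels) {
  m <- g$counts
  nr <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  j <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  row_s <- rowSums(m)
  col_s <- colSums(m)
  jmax <- max(which(col_s > 0))
  pop_var <- function(x) mean((x - mean(x))^2)
  out <- c(
    short_run_emphasis = sum(m / j^2) / nr,
    long_run_emphasis = sum(m * j^2) / nr,
    grey_level_nonuniformity = sum(row_s^2) / nr,
    run_length_nonuniformity = sum(col_s^2) / nr,
    run_percentage = nr / n_voxels,
    low_grey_level_run_emphasis = sum(m / i^2) / nr,
    high_grey_level_run_emphasis = sum(m * i^2) / nr,
    short_run_low_grey_level_emphasis = sum(m / (i^2 * j^2)) / nr,
    short_run_high_grey_level_emphasis = sum(m * i^2 / j^2) / nr,
    long_run_low_grey_level_emphasis = sum(m * j^2 / i^2) / nr,
    long_run_high_grey_level_emphasis = sum(m * i^2 * j^2) / nr,
    intensity_variability = pop_var(row_s),
    run_length_variability = pop_var(col_s[1:jmax])
  )
  names(out) <- paste0("glrl_", names(out))
  out
}

#' Size-zone features
#'
#' The 13 size-zone features (Thibault conventions) on the matrix of
#' 26-connected equal-bin zones; intensity variability and size-zone
#' variability are the population variances of the marginal zone counts
#' (over all grey levels, and over sizes up to the largest zone).
#'
#' @param g result of [build_glszm()].
#' @param n_voxels number of VOI voxels (for zone percentage).
#' @return Named numeric vector of 13 values (prefixed `glszm_`).
#' @export
glszm_features <- function(g, n_voxels) {
  m <- g$counts
  nz <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  j <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  row_s <- rowSums(m)
  col_s <- colSums(m)
  jmax <- max(which(col_s > 0))
  pop_var <- function(x) mean((x - mean(x))^2)
  out <- c(
    short_zone_emphasis = sum(m / j^2) / nz,
    long_zone_emphasis = sum(m * j^2) / nz,
    intensity_nonuniformity = sum(row_s^2) / nz,
    zone_length_nonuniformity = sum(col_s^2) / nz,
    zone_percentage = nz / n_voxels,
    low_intensity_zone_emphasis = sum(m / i^2) / nz,
    high_intensity_zone_emphasis = sum(m * i^2) / nz,
    short_zone_low_intensity_emphasis = sum(m / (i^2 * j^2)) / nz,
    short_zone_high_intensity_emphasis = sum(m * i^2 / j^2) / nz,
    long_zone_low_intensity_emphasis = sum(m * j^2 / i^2) / nz,
    long_zone_high_intensity_emphasis = sum(m * i^2 * j^2) / nz,
    intensity_variability = pop_var(row_s),
    size_zone_variability = pop_var(col_s[1:jmax])
  )
  names(out) <- paste0("glszm_", names(out))
  out
}

#' Neighbourhood grey-tone difference features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and texture
#' strength from the per-level occupancies `p_i` and summed deviations
#' `s_i` from the 26-neighbourhood means. Coarseness uses
#' `1 / (eps + sum p_i s_i)` with `eps = 1e-12`, capped at `1e12`;
#' busyness uses the `0/0 = 0` convention.
#'
#' @param g result of [build_ngtdm()].
#' @return Named numeric vector of 5 values (prefixed `ngtdm_`).
#' @export
ngtdm_features <- function(g) {
  eps <- 1e-12
  nv <- g$n_valid
  p <- g$n_i / nv
  s <- g$s_i
  lev <- seq_along(p)
  occ <- p > 0
  ngp <- sum(occ)
  pi_ <- p[occ]; si_ <- s[occ]; gi <- lev[occ]
  coarse <- min(1 / (eps + sum(pi_ * si_)), 1e12)
  if (ngp > 1) {
    dif2 <- outer(gi, gi, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1))) *
      (sum(si_) / nv)
    denom <- sum(abs(outer(gi * pi_, gi * pi_, "-")))
    busy <- if (denom > 0) sum(pi_ * si_) / denom else 0
    pis <- pi_ * si_
    cplx <- sum(abs(outer(gi, gi, "-")) *
                  outer(pis, pis, "+") / outer(pi_, pi_, "+")) / nv
    strength <- sum(outer(pi_, pi_, "+") * dif2) / (eps + sum(si_))
  } else {
    contrast <- 0; busy <- 0; cplx <- 0
    strength <- sum(outer(pi_, pi_, "+") * 0) / (eps + sum(si_))
  }
  out <- c(coarseness = coarse, contrast = contrast, busyness = busy,
           complexity = cplx, texture_strength = strength)
  names(out) <- paste0("ngtdm_", names(out))
  out
}

#' All matrix-based texture features with directional averaging
#'
#' Computes the 25 second-order (GLCM + GLDM) and 31 high-order
#' (GLRLM + GLSZM + NGTDM) features of the catalogue. GLCM and GLDM
#' features are averaged over `nrow(directions) * length(distances)`
#' offset matrices (default 7 x 2 = 14); GLRLM features over the 7
#' directions at step 1 (runs are contiguous by definition); GLSZM and
#' NGTDM are orientation-free and computed once. Offsets along which
#' the VOI admits no pair are excluded from the average; if a whole
#' family has no valid matrix its features are returned as `NA` with a
#' flag.
#'
#' @param q a [quantize_voi()] result.
#' @param directions integer matrix of direction rows
#'   (default [default_directions()]).
#' @param distances integer distance multipliers for GLCM/GLDM offsets.
#' @return Named numeric vector of 56 values with a `flags` attribute.
#' @export
matrix_features <- function(q, directions = default_directions(),
                            distances = c(1L, 2L)) {
  stopifnot(inherits(q, "quantized_voi"))
  flags <- character(0)
  offs <- do.call(rbind, lapply(distances, function(d) directions * d))

  avg_family <- function(per_matrix, template) {
    per_matrix <- per_matrix[!vapply(per_matrix, is.null, logical(1))]
    if (length(per_matrix) == 0) {
      out <- rep(NA_real_, length(template))
      names(out) <- template
      return(out)
    }
    colMeans(do.call(rbind, per_matrix))
  }

  glcm_list <- vector("list", nrow(offs))
  gldm_list <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    g <- build_glcm(q, offs[r, ])
    if (!g$empty) {
      f <- glcm_features(g)
      flags <- union(flags, attr(f, "flags"))
      glcm_list[[r]] <- f
    }
    h <- build_gldm(q, offs[r, ])
    if (!h$empty) gldm_list[[r]] <- gldm_features(h)
  }
  glcm_names <- paste0("glcm_", c(
    "autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "difference_variance",
    "dissimilarity", "energy", "entropy", "homogeneity",
    "information_measure_correlation_1", "information_measure_correlation_2",
    "inverse_difference_moment", "inverse_difference_moment_normalised",
    "inverse_difference_normalised", "maximum_probability", "sum_average",
    "sum_entropy", "sum_of_squares_variance", "sum_variance"))
  gldm_names <- paste0("gldm_", c("mean", "entropy", "variance", "contrast"))
  glcm_avg <- avg_family(glcm_list, glcm_names)
  gldm_avg <- avg_family(gldm_list, gldm_names)
  if (all(vapply(glcm_list, is.null, logical(1)))) {
    flags <- c(flags, "glcm_all_offsets_empty")
  }

  glrl_list <- vector("list", nrow(directions))
  for (r in seq_len(nrow(directions))) {
    g <- build_glrlm(q, directions[r, ])
    if (!g$empty) glrl_list[[r]] <- glrlm_features(g, q$n_voxels)
  }
  glrl_names <- paste0("glrl_", c(
    "short_run_emphasis", "long_run_emphasis", "grey_level_nonuniformity",
    "run_length_nonuniformity", "run_percentage",
    "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
    "short_run_low_grey_level_emphasis",
    "short_run_high_grey_level_emphasis",
    "long_run_low_grey_level_emphasis",
    "long_run_high_grey_level_emphasis",
    "intensity_variability", "run_length_variability"))
  glrl_avg <- avg_family(glrl_list, glrl_names)

  gz <- build_glszm(q)
  if (gz$empty) {
    glszm <- setNames(rep(NA_real_, 13),
                      paste0("glszm_", c("short_zone_emphasis",
                                         "long_zone_emphasis",
                                         "intensity_nonuniformity",
                                         "zone_length_nonuniformity",
                                         "zone_percentage",
                                         "low_intensity_zone_emphasis",
                                         "high_intensity_zone_emphasis",
                                         "short_zone_low_intensity_emphasis",
                                         "short_zone_high_intensity_emphasis",
                                         "long_zone_low_intensity_emphasis",
                                         "long_zone_high_intensity_emphasis",
                                         "intensity_variability",
                                         "size_zone_variability")))
    flags <- c(flags, "glszm_empty")
  } else {
    glszm <- glszm_features(gz, q$n_voxels)
  }

  gn <- build_ngtdm(q)
  if (gn$empty) {
    ngtdm <- setNames(rep(NA_real_, 5),
                      paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                         "complexity", "texture_strength")))
    flags <- c(flags, "ngtdm_all_voxels_neighbourless")
  } else {
    ngtdm <- ngtdm_features(gn)
  }

  out <- c(glcm_avg, gldm_avg, glrl_avg, glszm, ngtdm)
  attr(out, "flags") <- flags
  out
}
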