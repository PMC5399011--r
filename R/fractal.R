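#' Fractal texture features
#'
#' Six model-based descriptors of the intensity surface over the VOI
#' bounding box: mean and SD of local differential box-counting (DBC)
#' fractal dimensions, their reciprocal, gliding-box lacunarity, the
#' Hurst exponent from the isotropic variogram, and the mean blanket
#' (Peleg) dimension over the same window grid.
#'
#' @name fractal
NULL

# bounding-box subarrays of intensity and mask, padded by edge
# replication to a multiple of window_vox on each axis
fractal_bbox <- function(volume, mask, window_vox = NULL) {
  voi <- extract_voi(volume, mask)
  rng <- apply(voi$index, 2, range)
  idx <- lapply(1:3, function(a) rng[1, a]:rng[2, a])
  vol_bb <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  msk_bb <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (!is.null(window_vox)) {
    d <- dim(vol_bb)
    pad <- lapply(1:3, function(a) pmin(seq_len(ceiling(d[a] / window_vox) *
                                                  window_vox), d[a]))
    vol_bb <- vol_bb[pad[[1]], pad[[2]], pad[[3]], drop = FALSE]
    msk_bb <- msk_bb[pad[[1]], pad[[2]], pad[[3]], drop = FALSE]
  }
  list(vol = vol_bb, mask = msk_bb)
}

rescale_grey <- function(arr, g_levels = 64) {
  lo <- min(arr); hi <- max(arr)
  if (hi <= lo) return(array(0, dim(arr)))
  (arr - lo) / (hi - lo) * (g_levels - 1)
}

window_starts <- function(d, w) {
  lapply(1:3, function(a) seq(1, d[a], by = w))
}

#' Local fractal dimension by differential box counting
#'
#' The bounding box of the VOI is rescaled to grey levels `[0, G-1]`
#' (G = 64), padded by edge replication and tiled into cubic windows of
#' `window_vox` voxels. Per window and box size `s`, the window is
#' partitioned into `s x s x s` spatial columns; with grey-box height
#' `h = s * G / window_vox` each column contributes
#' `ceil(max/h) - ceil(min/h) + 1` boxes, and the fractal dimension is
#' the least-squares slope of `log N_s` versus `log(1/s)`. A flat
#' intensity surface gives dimension 3 and the column count bounds the
#' estimate in `[3, 4]`.
#'
#' @inheritParams extract_voi
#' @param window_vox window edge length in voxels (default 8).
#' @param box_sizes box-size ladder; each must divide `window_vox`.
#' @param g_levels grey-level range for the rescaled intensities.
#' @return An `fd_map` list with `fd` (per-window estimates),
#'   `window_vox`, `box_sizes`.
#' @export
dbc_local_fd <- function(volume, mask, window_vox = 8,
                         box_sizes = c(2, 4, 8), g_levels = 64) {
  stopifnot(window_vox >= max(box_sizes), min(box_sizes) >= 2,
            all(window_vox %% box_sizes == 0), length(box_sizes) >= 2)
  bb <- fractal_bbox(volume, mask, window_vox)
  grey <- rescale_grey(bb$vol, g_levels)
  st <- window_starts(dim(grey), window_vox)
  fds <- c()
  for (k in st[[3]]) for (j in st[[2]]) for (i in st[[1]]) {
    win <- grey[i:(i + window_vox - 1), j:(j + window_vox - 1),
                k:(k + window_vox - 1)]
    ns <- vapply(box_sizes, function(s) dbc_count(win, s, g_levels),
                 numeric(1))
    ok <- is.finite(ns) & ns > 0
    if (sum(ok) < 2) next
    fit <- stats::lm.fit(cbind(1, log(1 / box_sizes[ok])), log(ns[ok]))
    fds <- c(fds, fit$coefficients[2])
  }
  if (length(fds) == 0) {
    stop("dbc_local_fd: no window produced a valid box-count regression",
         call. = FALSE)
  }
  structure(list(fd = as.numeric(fds), window_vox = window_vox,
                 box_sizes = box_sizes), class = "fd_map")
}

# box count for one window at box size s (differential box counting)
dbc_count <- function(win, s, g_levels) {
  w <- dim(win)[1]
  h <- s * g_levels / w
  b <- array(win, dim = c(s, w / s, s, w / s, s, w / s))
  mx <- apply(b, c(2, 4, 6), max)
  mn <- apply(b, c(2, 4, 6), min)
  sum(ceiling(mx / h) - ceiling(mn / h) + 1)
}

#' Summaries of a local fractal-dimension map
#'
#' @param map an `fd_map` from [dbc_local_fd()].
#' @return Named vector `c(fd_mean, fd_sd, fd_inverse)`; the SD is the
#'   population SD over windows and `fd_inverse = 1 / fd_mean`.
#' @export
fd_summary <- function(map) {
  stopifnot(inherits(map, "fd_map"), length(map$fd) >= 1)
  m <- mean(map$fd)
  c(fd_mean = m,
    fd_sd = sqrt(mean((map$fd - m)^2)),
    fd_inverse = 1 / m)
}

#' Gliding-box lacunarity
#'
#' For each box size `s`, all `s^3` boxes gliding at stride 1 inside
#' the VOI bounding box give masses `S`; the lacunarity at that size is
#' the moment ratio `M2 / M1^2 - 1 = var(S) / mean(S)^2`, and the
#' feature is the mean over the box-size ladder. Invariant under
#' intensity scaling; zero for a constant volume.
#'
#' @inheritParams extract_voi
#' @param box_sizes gliding-box edge lengths in voxels.
#' @return Scalar lacunarity.
#' @export
lacunarity <- function(volume, mask, box_sizes = c(2, 4, 8)) {
  bb <- fractal_bbox(volume, mask)
  arr <- bb$vol
  d <- dim(arr)
  lam <- c()
  for (s in box_sizes) {
    if (any(d < s)) next
    masses <- gliding_box_sums(arr, s)
    m1 <- mean(masses)
    if (m1 == 0) stop("lacunarity: zero mean box mass", call. = FALSE)
    lam <- c(lam, mean(masses^2) / m1^2 - 1)
  }
  if (length(lam) == 0) {
    stop("lacunarity: VOI bounding box smaller than every box size",
         call. = FALSE)
  }
  mean(lam)
}

# all s^3 box sums at stride 1 via a 3D summed-area table
gliding_box_sums <- function(arr, s) {
  d <- dim(arr)
  cs <- arr
  for (a in 1:3) cs <- apply(cs, setdiff(1:3, a), cumsum) |>
      aperm(order(c(a, setdiff(1:3, a))))
  pad <- array(0, d + 1)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cs
  i <- 1:(d[1] - s + 1); j <- 1:(d[2] - s + 1); k <- 1:(d[3] - s + 1)
  box <- pad[i + s, j + s, k + s, drop = FALSE] -
    pad[i, j + s, k + s, drop = FALSE] -
    pad[i + s, j, k + s, drop = FALSE] -
    pad[i + s, j + s, k, drop = FALSE] +
    pad[i, j, k + s, drop = FALSE] +
    pad[i, j + s, k, drop = FALSE] +
    pad[i + s, j, k, drop = FALSE] -
    pad[i, j, k, drop = FALSE]
  as.numeric(box)
}

#' Blanket (Peleg) fractal dimension
#'
#' Upper and lower blanket surfaces are grown by iterated +/-1
#' dilation/erosion with a 6-neighbour max/min; the surface area at
#' scale `e` is `A(e) = sum(u_e - l_e) / (2e)` and the dimension is
#' `3 - slope` of `log A(e)` versus `log e`. Computed per window of the
#' same grid as [dbc_local_fd()] on the grey-rescaled bounding box, and
#' averaged. A flat window gives exactly 3.
#'
#' @inheritParams dbc_local_fd
#' @param n_dilations number of blanket iterations (>= 2).
#' @return Scalar mean blanket dimension.
#' @export
blanket_fd <- function(volume, mask, n_dilations = 5, window_vox = 8,
                       g_levels = 64) {
  stopifnot(n_dilations >= 2)
  bb <- fractal_bbox(volume, mask, window_vox)
  grey <- rescale_grey(bb$vol, g_levels)
  st <- window_starts(dim(grey), window_vox)
  fds <- c()
  for (k in st[[3]]) for (j in st[[2]]) for (i in st[[1]]) {
    win <- grey[i:(i + window_vox - 1), j:(j + window_vox - 1),
                k:(k + window_vox - 1)]
    u <- win; l <- win
    area <- numeric(n_dilations)
    for (e in seq_len(n_dilations)) {
      u <- pmax(u + 1, neighbour_extreme(u, pmax))
      l <- pmin(l - 1, neighbour_extreme(l, pmin))
      area[e] <- sum(u - l) / (2 * e)
    }
    fit <- stats::lm.fit(cbind(1, log(seq_len(n_dilations))), log(area))
    fds <- c(fds, 3 - fit$coefficients[2])
  }
  if (length(fds) == 0) {
    stop("blanket_fd: degenerate blanket regression", call. = FALSE)
  }
  mean(fds)
}

# elementwise max/min over the 6 axis neighbours (edge-replicated)
neighbour_extreme <- function(arr, fun) {
  d <- dim(arr)
  out <- arr
  for (a in 1:3) {
    lo <- pmax(seq_len(d[a]) - 1, 1)
    hi <- pmin(seq_len(d[a]) + 1, d[a])
    if (a == 1) {
      out <- fun(out, arr[lo, , , drop = FALSE], arr[hi, , , drop = FALSE])
    } else if (a == 2) {
      out <- fun(out, arr[, lo, , drop = FALSE], arr[, hi, , drop = FALSE])
    } else {
      out <- fun(out, arr[, , lo, drop = FALSE], arr[, , hi, drop = FALSE])
    }
  }
  out
}

#' Hurst exponent from the isotropic variogram
#'
#' Mean squared intensity increments between in-VOI voxel pairs are
#' computed at lags 1..`n_lags` voxels along each axis; the semivariance
#' is regressed on lag distance (mm) on log-log axes and the Hurst
#' exponent is half the slope. Invariant under positive affine
#' intensity maps. A constant VOI is degenerate and returns 0 with a
#' `flags` attribute.
#'
#' @inheritParams extract_voi
#' @param n_lags number of voxel lags per axis (default 4).
#' @return Scalar estimate with optional `flags` attribute.
#' @export
hurst_exponent <- function(volume, mask, n_lags = 4) {
  bb <- fractal_bbox(volume, mask)
  arr <- bb$vol
  msk <- bb$mask != 0L
  d <- dim(arr)
  dists <- c(); gammas <- c()
  for (a in 1:3) {
    for (l in seq_len(n_lags)) {
      if (d[a] <= l) next
      n <- d[a]
      i1 <- 1:(n - l); i2 <- (l + 1):n
      if (a == 1) {
        x1 <- arr[i1, , , drop = FALSE]; x2 <- arr[i2, , , drop = FALSE]
        m12 <- msk[i1, , , drop = FALSE] & msk[i2, , , drop = FALSE]
      } else if (a == 2) {
        x1 <- arr[, i1, , drop = FALSE]; x2 <- arr[, i2, , drop = FALSE]
        m12 <- msk[, i1, , drop = FALSE] & msk[, i2, , drop = FALSE]
      } else {
        x1 <- arr[, , i1, drop = FALSE]; x2 <- arr[, , i2, drop = FALSE]
        m12 <- msk[, , i1, drop = FALSE] & msk[, , i2, drop = FALSE]
      }
      if (!any(m12)) next
      g <- mean((x1[m12] - x2[m12])^2) / 2
      dists <- c(dists, l * volume$spacing[a])
      gammas <- c(gammas, g)
    }
  }
  pos <- gammas > 0
  if (sum(pos) < 2 || length(unique(dists[pos])) < 2) {
    if (all(gammas == 0)) {
      return(structure(0, flags = "hurst_degenerate_constant"))
    }
    stop("hurst_exponent: fewer than 2 valid lags", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(dists[pos])), log(gammas[pos]))
  as.numeric(fit$coefficients[2] / 2)
}

#' All six fractal features
#'
#' @inheritParams dbc_local_fd
#' @param n_dilations blanket iterations.
#' @param n_lags variogram lags.
#' @return Named numeric vector `fd_mean, fd_sd, fd_lacunarity,
#'   fd_hurst_exponent, fd_blanket_mean, fd_inverse`.
#' @export
fractal_features <- function(volume, mask, window_vox = 8,
                             box_sizes = c(2, 4, 8), n_dilations = 5,
                             n_lags = 4) {
  fs <- fd_summary(dbc_local_fd(volume, mask, window_vox, box_sizes))
  c(fd_mean = fs[["fd_mean"]],
    fd_sd = fs[["fd_sd"]],
    fd_lacunarity = lacunarity(volume, mask, box_sizes),
    fd_hurst_exponent = as.numeric(hurst_exponent(volume, mask, n_lags)),
    fd_blanket_mean = blanket_fd(volume, mask, n_dilations, window_vox),
    fd_inverse = fs[["fd_inverse"]])
}
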