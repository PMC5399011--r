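# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (triple loops, explicit enumeration) and never share
# code with the package internals they check.

make_vol <- function(arr, spacing = c(1, 1, 1), units = "ARBITRARY") {
  scalar_volume(arr, spacing = spacing, units = units)
}

make_mask_full <- function(dims, spacing = c(1, 1, 1)) {
  voi_mask(array(1L, dims), spacing = spacing)
}

# quantized_voi built directly from a bin array (0 = outside VOI)
qv_from_bins <- function(bins, n_bins = max(bins), spacing = c(1, 1, 1)) {
  storage.mode(bins) <- "integer"
  fg <- which(bins != 0L)
  structure(list(bin_array = bins, values = as.numeric(bins[fg]),
                 bin = bins[fg],
                 edges = seq(0, n_bins, length.out = n_bins + 1),
                 n_bins = as.integer(n_bins), spacing = spacing,
                 n_voxels = length(fg)),
            class = "quantized_voi")
}

rand_bins <- function(dims, n_bins = 4, p_voi = 0.8) {
  b <- array(sample(0:n_bins, prod(dims), replace = TRUE,
                    prob = c(1 - p_voi, rep(p_voi / n_bins, n_bins))),
             dim = dims)
  b
}

in_grid <- function(i, d) all(i >= 1 & i <= d)

naive_glcm <- function(bins, offset, n_bins) {
  d <- dim(bins)
  m <- matrix(0, n_bins, n_bins)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- bins[i, j, k]
    if (a == 0) next
    t <- c(i, j, k) + offset
    if (!in_grid(t, d)) next
    b <- bins[t[1], t[2], t[3]]
    if (b == 0) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

naive_gldm <- function(bins, offset, n_bins) {
  d <- dim(bins)
  h <- numeric(n_bins)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- bins[i, j, k]
    if (a == 0) next
    t <- c(i, j, k) + offset
    if (!in_grid(t, d)) next
    b <- bins[t[1], t[2], t[3]]
    if (b == 0) next
    h[abs(a - b) + 1] <- h[abs(a - b) + 1] + 1
  }
  h
}

naive_glrlm <- function(bins, dir, n_bins) {
  d <- dim(bins)
  maxlen <- max(d)
  m <- matrix(0, n_bins, maxlen)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- bins[i, j, k]
    if (a == 0) next
    prev <- c(i, j, k) - dir
    if (in_grid(prev, d) && bins[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    nxt <- c(i, j, k) + dir
    while (in_grid(nxt, d) && bins[nxt[1], nxt[2], nxt[3]] == a) {
      len <- len + 1
      nxt <- nxt + dir
    }
    m[a, len] <- m[a, len] + 1
  }
  m
}

# zone sizes per grey level by breadth-first search over 26-neighbours
naive_glszm_zones <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  zones <- list()
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (s in which(bins != 0 & !seen)) {
    if (seen[s]) next
    a <- bins[s]
    queue <- list(arrayInd(s, d)[1, ])
    seen[s] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(nb))) {
        w <- v + nb[r, ]
        if (!in_grid(w, d)) next
        if (seen[w[1], w[2], w[3]]) next
        if (bins[w[1], w[2], w[3]] != a) next
        seen[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = a, size = size)
  }
  do.call(rbind, zones)
}

naive_ngtdm <- function(bins, n_bins) {
  d <- dim(bins)
  n_i <- numeric(n_bins)
  s_i <- numeric(n_bins)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- bins[i, j, k]
    if (a == 0) next
    vals <- c()
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      t <- c(i + di, j + dj, k + dk)
      if (!in_grid(t, d)) next
      b <- bins[t[1], t[2], t[3]]
      if (b != 0) vals <- c(vals, b)
    }
    if (length(vals) == 0) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  list(n_i = n_i, s_i = s_i)
}

# exact two-sided signed-rank p by full enumeration of sign assignments
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  min(1, p)
}

# isotropic fractional-Brownian-like field by spectral synthesis:
# Gaussian spectrum with amplitude |k|^-(H + dim/2)
fbm_field_3d <- function(n, hurst, seed) {
  set.seed(seed)
  f <- seq(0, n - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  k2 <- outer(outer(f^2, f^2, "+"), f^2, "+")
  amp <- k2^(-(hurst + 3 / 2) / 2)
  amp[1, 1, 1] <- 0
  ph <- array(complex(modulus = 1, argument = runif(n^3, -pi, pi)), dim(k2))
  g <- Re(fft(amp * ph, inverse = TRUE))
  (g - mean(g)) / sd(g)
}
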