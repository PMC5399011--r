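test_that("GLCM on the 2x2 hand example reproduces enumerated pair counts", {
  bins <- array(0L, c(2, 2, 1))
  bins[1, 1, 1] <- 1L; bins[2, 1, 1] <- 1L
  bins[1, 2, 1] <- 1L; bins[2, 2, 1] <- 2L
  q <- qv_from_bins(bins, n_bins = 2)
  g <- build_glcm(q, c(0, 1, 0))
  expect_false(g$empty)
  expect_equal(g$p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  f <- glcm_features(g)
  expect_equal(f[["glcm_contrast"]], 0.5)
  expect_equal(f[["glcm_dissimilarity"]], 0.5)
  expect_equal(f[["glcm_energy"]], 0.375)
  expect_equal(f[["glcm_maximum_probability"]], 0.5)
})

test_that("constant VOI gives the degenerate single-cell co-occurrence", {
  bins <- array(1L, c(3, 3, 3))
  q <- qv_from_bins(bins, n_bins = 64)
  g <- build_glcm(q, c(1, 0, 0))
  f <- glcm_features(g)
  expect_equal(f[["glcm_energy"]], 1)
  expect_equal(f[["glcm_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_maximum_probability"]], 1)
  expect_equal(f[["glcm_homogeneity"]], 1)
  expect_true("glcm_zero_marginal_variance" %in% attr(f, "flags"))
  expect_equal(f[["glcm_correlation"]], 0)
})

test_that("uniform co-occurrence over k^2 cells has entropy 2 log2 k", {
  for (k in c(2, 4, 8)) {
    g <- list(p = matrix(1 / k^2, k, k), empty = FALSE)
    expect_equal(glcm_features(g)[["glcm_entropy"]], 2 * log2(k))
  }
})

test_that("co-occurrence matrices are symmetric and match the naive oracle", {
  set.seed(10)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                c(1, 0, 1), c(0, 1, 1), c(1, 1, 1), c(2, 0, 0), c(2, 2, 2))
  for (i in 1:20) {
    bins <- rand_bins(c(4, 4, 3), n_bins = 4)
    q <- qv_from_bins(bins, n_bins = 4)
    for (r in seq_len(nrow(offs))) {
      g <- build_glcm(q, offs[r, ])
      expect_identical(g$counts, naive_glcm(bins, offs[r, ], 4))
      expect_identical(g$counts, t(g$counts))
      h <- build_gldm(q, offs[r, ])
      expect_identical(as.numeric(h$counts), naive_gldm(bins, offs[r, ], 4))
    }
  }
})

test_that("GLDM matches the GLCM redundancies exactly (identity suite)", {
  set.seed(11)
  for (i in 1:30) {
    bins <- rand_bins(c(4, 4, 3), n_bins = 5)
    if (sum(bins > 0) < 4) next
    q <- qv_from_bins(bins, n_bins = 5)
    off <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))[sample(3, 1), ]
    g <- build_glcm(q, off); h <- build_gldm(q, off)
    if (g$empty) next
    fg <- glcm_features(g); fh <- gldm_features(h)
    expect_equal(fg[["glcm_dissimilarity"]], fh[["gldm_mean"]],
                 tolerance = 1e-9)
    expect_equal(fg[["glcm_contrast"]], fh[["gldm_contrast"]],
                 tolerance = 1e-9)
    expect_equal(fg[["glcm_contrast"]], fg[["glcm_difference_variance"]],
                 tolerance = 1e-9)
    expect_equal(fg[["glcm_difference_entropy"]], fh[["gldm_entropy"]],
                 tolerance = 1e-9)
    expect_equal(fg[["glcm_homogeneity"]],
                 fg[["glcm_inverse_difference_moment"]], tolerance = 1e-9)
  }
})

test_that("run-length matrices follow hand enumeration and conservation", {
  bins <- array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1))
  q <- qv_from_bins(bins, n_bins = 2)
  g <- build_glrlm(q, c(1, 0, 0))
  expect_equal(g$n_runs, 2)
  f <- glrlm_features(g, q$n_voxels)
  expect_equal(f[["glrl_short_run_emphasis"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(f[["glrl_long_run_emphasis"]], 6.5)
  expect_equal(f[["glrl_run_percentage"]], 2 / 5)

  # constant line of length L: one run, LRE = L^2, RP = 1/L
  for (L in c(3, 7)) {
    qc <- qv_from_bins(array(1L, c(L, 1, 1)), n_bins = 2)
    fc <- glrlm_features(build_glrlm(qc, c(1, 0, 0)), L)
    expect_equal(fc[["glrl_long_run_emphasis"]], L^2)
    expect_equal(fc[["glrl_run_percentage"]], 1 / L)
  }

  # sum_j j * r(i, j) equals the VOI voxel count, any direction
  set.seed(12)
  dirs <- default_directions()
  for (i in 1:15) {
    bins <- rand_bins(c(4, 4, 3), n_bins = 3)
    if (sum(bins > 0) == 0) next
    q <- qv_from_bins(bins, n_bins = 3)
    for (r in seq_len(nrow(dirs))) {
      m <- build_glrlm(q, dirs[r, ])$counts
      expect_equal(sum(m %*% seq_len(ncol(m))), sum(bins > 0))
      expect_identical(m, naive_glrlm(bins, dirs[r, ], 3))
    }
  }
})

test_that("size zones are 26-connected components matching the BFS oracle", {
  # constant VOI: one zone of size N
  bins <- array(1L, c(3, 3, 2))
  q <- qv_from_bins(bins, n_bins = 2)
  g <- build_glszm(q)
  expect_equal(g$n_zones, 1)
  f <- glszm_features(g, 18)
  expect_equal(f[["glszm_zone_percentage"]], 1 / 18)
  expect_equal(f[["glszm_long_zone_emphasis"]], 18^2)

  # checkerboard slice: diagonal connectivity merges same-bin squares
  cb <- array(0L, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) cb[i, j, 1] <- 1L + (i + j) %% 2L
  zq <- build_glszm(qv_from_bins(cb, n_bins = 2))
  oracle <- naive_glszm_zones(cb)
  expect_equal(zq$n_zones, nrow(oracle))
  expect_equal(sort(rep(seq_len(nrow(zq$counts)),
                        times = rowSums(zq$counts))),
               sort(oracle[, "level"]))
  expect_equal(zq$n_zones, 2)

  set.seed(13)
  for (i in 1:15) {
    bins <- rand_bins(c(4, 4, 3), n_bins = 3)
    if (sum(bins > 0) == 0) next
    q <- qv_from_bins(bins, n_bins = 3)
    g <- build_glszm(q)
    oz <- naive_glszm_zones(bins)
    # compare multisets of (level, size)
    mine <- cbind(level = rep(seq_len(nrow(g$counts)), ncol(g$counts)),
                  size = rep(seq_len(ncol(g$counts)),
                             each = nrow(g$counts)))
    mine <- mine[as.vector(g$counts) > 0, , drop = FALSE]
    cnt <- as.vector(g$counts)[as.vector(g$counts) > 0]
    mine <- mine[rep(seq_len(nrow(mine)), cnt), , drop = FALSE]
    expect_equal(mine[order(mine[, 1], mine[, 2]), , drop = FALSE],
                 oz[order(oz[, 1], oz[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    # conservation: sum_j j * z(i, j) = N
    expect_equal(sum(g$counts %*% seq_len(ncol(g$counts))), sum(bins > 0))
  }
})

test_that("NGTDM matches the naive neighbourhood oracle and degenerates safely", {
  # constant VOI: s_i = 0 everywhere
  q <- qv_from_bins(array(1L, c(3, 3, 3)), n_bins = 2)
  f <- ngtdm_features(build_ngtdm(q))
  expect_equal(f[["ngtdm_contrast"]], 0)
  expect_equal(f[["ngtdm_busyness"]], 0)
  expect_equal(f[["ngtdm_coarseness"]], 1e12)

  # two-level alternation and random fields vs brute force
  set.seed(14)
  alt <- array(rep(c(1L, 2L), 6), c(4, 3, 1))
  cases <- c(list(alt), lapply(1:10, function(i) rand_bins(c(4, 4, 3), 3)))
  for (bins in cases) {
    if (sum(bins > 0) == 0) next
    q <- qv_from_bins(bins, n_bins = max(2, max(bins)))
    g <- build_ngtdm(q)
    o <- naive_ngtdm(bins, q$n_bins)
    expect_equal(g$n_i, o$n_i)
    expect_equal(g$s_i, o$s_i, tolerance = 1e-9)
    if (!g$empty) {
      p <- g$n_i / g$n_valid
      expect_equal(sum(p[p > 0]), 1)
    }
  }
})

test_that("directional averaging: order-invariant, empty offsets excluded,
           anisotropy averaged between extremes", {
  set.seed(15)
  bins <- rand_bins(c(5, 5, 4), n_bins = 4, p_voi = 1)
  q <- qv_from_bins(bins, n_bins = 4)
  dirs <- default_directions()
  f1 <- matrix_features(q, dirs)
  f2 <- matrix_features(q, dirs[sample(7), ])
  expect_equal(f1, f2, tolerance = 1e-12, ignore_attr = TRUE)

  # stripes varying along x only: contrast along x is maximal, along the
  # stripe (y) zero; the average lies strictly between
  st <- array(rep(rep(c(1L, 2L), length.out = 6), times = 6 * 4), c(6, 6, 4))
  qs <- qv_from_bins(st, n_bins = 2)
  fx <- glcm_features(build_glcm(qs, c(1, 0, 0)))[["glcm_contrast"]]
  fy <- glcm_features(build_glcm(qs, c(0, 1, 0)))[["glcm_contrast"]]
  fa <- matrix_features(qs)[["glcm_contrast"]]
  expect_gt(fx, fy)
  expect_gt(fa, fy)
  expect_lt(fa, fx)

  # single-slice VOI: z offsets admit no pair but the average still exists
  sl <- array(0L, c(4, 4, 3)); sl[, , 2] <- rand_bins(c(4, 4, 1), 3)[, , 1]
  if (sum(sl > 0) > 4) {
    qsl <- qv_from_bins(sl, n_bins = 3)
    fsl <- matrix_features(qsl)
    expect_false(anyNA(fsl[grep("glcm", names(fsl))]))
  }
  expect_true(build_glcm(qv_from_bins(array(c(1L, rep(0L, 11)), c(4, 3, 1)),
                                      2), c(1, 0, 0))$empty)
})

test_that("averaged features respect the direction-set symmetries", {
  # the default direction set is closed under xy-swap and inversion, so
  # transposing the first two axes (and flipping all axes) leaves every
  # averaged feature unchanged
  set.seed(16)
  bins <- rand_bins(c(5, 4, 4), n_bins = 4, p_voi = 0.9)
  q1 <- qv_from_bins(bins, n_bins = 4)
  swapped <- aperm(bins, c(2, 1, 3))
  q2 <- qv_from_bins(swapped, n_bins = 4)
  flipped <- bins[dim(bins)[1]:1, dim(bins)[2]:1, dim(bins)[3]:1]
  q3 <- qv_from_bins(flipped, n_bins = 4)
  f1 <- matrix_features(q1); f2 <- matrix_features(q2)
  f3 <- matrix_features(q3)
  expect_equal(f1, f2, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f1, f3, tolerance = 1e-9, ignore_attr = TRUE)
})
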