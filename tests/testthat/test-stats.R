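test_that("signed-rank test: degenerate and small-sample exact cases", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 2.8)
  w <- wilcoxon_signed_rank(x, x)
  expect_equal(w$p, 1)
  expect_true("all_differences_zero" %in% w$flags)

  # n = 6, all shifted one way: exact p = 2/64
  w6 <- wilcoxon_signed_rank(x, x + seq(0.1, 0.6, by = 0.1))
  expect_equal(w6$p, 2 / 64)
  expect_equal(w6$method, "exact")

  # n = 5 cannot reach p < 0.05 two-sided
  w5 <- wilcoxon_signed_rank(x[1:5], x[1:5] + c(1, 2, 3, 4, 5))
  expect_equal(w5$p, 2 / 32)

  expect_error(wilcoxon_signed_rank(1:4, c(2, 3, 4, 5)), "fewer than 5")
})

test_that("signed-rank exact branch agrees with full sign enumeration", {
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:11, 1)
    d <- round(rnorm(n, sd = 3), 2)
    d <- d[d != 0]
    if (length(d) < 5) next
    if (any(duplicated(abs(d)))) next
    e <- rnorm(length(d))
    w <- wilcoxon_signed_rank(e, e + d)
    expect_equal(w$p, enum_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank p is invariant under strictly monotone transforms", {
  set.seed(31)
  e <- rlnorm(12); l <- rlnorm(12) * 1.3
  p0 <- wilcoxon_signed_rank(e, l)$p
  # monotone maps applied to both arms preserve difference signs only if
  # applied pairwise-consistently; rank-based p depends on the differences'
  # rank pattern, so test the transform on a location family
  d <- l - e
  for (f in list(function(z) 2 * z + 5, function(z) z * 10)) {
    expect_equal(wilcoxon_signed_rank(f(e), f(e + d))$p, p0)
  }
})

test_that("normal-approximation branch tracks the exact branch at n = 25", {
  set.seed(32)
  for (i in 1:20) {
    e <- rnorm(25); l <- rnorm(25, mean = 0.2)
    pe <- wilcoxon_signed_rank(e, l, exact_max = 25)$p
    pa <- wilcoxon_signed_rank(e, l, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("tied data fall back to the tie-corrected approximation", {
  set.seed(33)
  e <- rep(1:5, 3)
  l <- e + sample(rep(c(-2, -1, 1, 2, 3), 3))
  w <- wilcoxon_signed_rank(e, l)
  expect_equal(w$method, "normal_approx")
  expect_true(w$p >= 0 && w$p <= 1)
})

test_that("Spearman correlation handles perfect, reversed and tied ranks", {
  expect_equal(spearman_rank(1:8, (1:8)^3)$r, 1)
  expect_equal(spearman_rank(1:8, 9 - (1:8))$r, -1)
  s <- spearman_rank(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(s$r, 1 - 6 * 2 / (4 * 15)) # 0.8
  expect_equal(spearman_rank(c(1, 1, 1, 1), 1:4)$flags, "zero_rank_variance")
  # agrees with the reference implementation on random data with ties
  set.seed(34)
  for (i in 1:10) {
    x <- sample(1:6, 20, replace = TRUE)
    y <- x + rnorm(20)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    got <- spearman_rank(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-9)
  }
})

test_that("ICC(2,1): perfect agreement, shuffled raters, offset penalty", {
  set.seed(35)
  a <- rnorm(20, 10, 3)
  expect_equal(icc_agreement(cbind(a, a))$icc, 1)

  b <- rnorm(200, 10, 3)
  shuf <- icc_agreement(cbind(b, sample(b)))$icc
  expect_lt(abs(shuf), 0.15)

  # constant offset: hand-computed mean squares on a 5-subject fixture
  x <- c(1, 2, 3, 4, 5)
  m <- cbind(x, x + 2)
  n <- 5; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_agreement(m)$icc
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(got, 1)
  expect_gt(got, 0.5)
})

test_that("comparison table: identical time points give no directions", {
  cat_names <- feature_catalog()$feature
  set.seed(36)
  one <- tibble::as_tibble(as.list(setNames(rnorm(99), cat_names)))
  feats <- dplyr::bind_rows(lapply(1:8, function(i) one + i))
  feats <- dplyr::bind_rows(feats, feats) |>
    dplyr::mutate(patient_id = rep(sprintf("p%d", 1:8), 2),
                  group = "unknown",
                  timepoint = rep(c("early", "late"), each = 8),
                  .before = 1)
  cmp <- compare_timepoints(feats)
  tab <- tidy(cmp)
  expect_true(all(tab$direction == "none"))
  expect_true(all(tab$wilcoxon_p == 1))
  expect_equal(nrow(tab), 99)
  expect_true(all(tab$early_min <= tab$early_median &
                    tab$early_median <= tab$early_max))
})

test_that("comparison table: noise-free benign washout pushes every
           mean-like SUV feature down", {
  spec <- phantom_spec(n_patients = 8, benign_fraction = 0.99,
                       grid_shape = c(14, 14, 12),
                       semi_axes_range_mm = c(8, 13),
                       noise_kappa = 0, washout = 0.8, seed = 11)
  coh <- generate_cohort(spec)
  feats <- extract_cohort_features(coh)
  cmp <- suppressWarnings(compare_timepoints(feats))
  tab <- tidy(cmp)
  down <- tab[tab$group == "all" &
                tab$feature %in% c("suv_mean", "suv_median",
                                   "suv_total_lesion_glycolysis",
                                   "suv_10th_percentile",
                                   "suv_90th_percentile", "suv_peak",
                                   "suv_maximum"), ]
  expect_true(all(down$direction == "down"))
  # row count: 99 features x eligible groups
  expect_equal(nrow(tab), 99 * length(cmp$groups))
})

test_that("family summary partitions significant counts and sums to totals", {
  spec <- phantom_spec(n_patients = 8, grid_shape = c(14, 14, 12),
                       semi_axes_range_mm = c(8, 13), washout = 0.7,
                       seed = 12)
  coh <- generate_cohort(spec)
  cmp <- suppressWarnings(compare_timepoints(extract_cohort_features(coh)))
  fs <- summarize_families(cmp)
  expect_true(all(fs$n_up + fs$n_down == fs$n_significant))
  fam <- fs[fs$family != "total", ]
  expect_setequal(unique(as.integer(fam$family_size)), c(37, 25, 31, 6))
  for (g in unique(fs$group)) {
    tot <- fs[fs$group == g & fs$family == "total", ]
    expect_equal(tot$n_significant,
                 sum(fam$n_significant[fam$group == g]))
    expect_equal(tot$family_size, 99L)
  }
  # all-null table gives zero counts
  cat_names <- feature_catalog()$feature
  one <- tibble::as_tibble(as.list(setNames(rnorm(99), cat_names)))
  nullf <- dplyr::bind_rows(lapply(1:6, function(i) one * i))
  nullf <- dplyr::bind_rows(nullf, nullf) |>
    dplyr::mutate(patient_id = rep(sprintf("p%d", 1:6), 2),
                  group = "unknown",
                  timepoint = rep(c("early", "late"), each = 6), .before = 1)
  fs0 <- summarize_families(compare_timepoints(nullf))
  expect_true(all(fs0$n_significant == 0))
})
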