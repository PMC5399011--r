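test_that("decay factor matches half-life arithmetic and is multiplicative", {
  expect_equal(decay_factor(0, 109.77), 1.0)
  expect_equal(decay_factor(109.77, 109.77), 2.0)
  expect_equal(decay_factor(219.54, 109.77), 4.0)
  expect_error(decay_factor(-1, 109.77), "negative")
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0, 300); b <- runif(1, 0, 300); hl <- runif(1, 50, 200)
    expect_equal(decay_factor(a + b, hl),
                 decay_factor(a, hl) * decay_factor(b, hl))
  }
})

test_that("SUV conversion follows the body-weight definition", {
  # c = 5000 Bq/ml, A = 350 MBq, dt = one half-life, W = 70 kg -> SUV 2
  v <- scalar_volume(array(5000, c(3, 3, 3)), c(4.7, 4.7, 3.27),
                     units = "ACTIVITY_BQ_ML")
  meta <- acquisition_meta(350, 70, uptake_time_min = 109.77)
  s <- to_suv(v, meta)
  expect_equal(s$data[1], 5000 / (175e6 / 70000))
  expect_equal(s$data[1], 2.0)
  expect_equal(s$units, "SUV")

  # activity spread over a volume numerically equal to body weight in g
  # gives SUV 1 at dt = 0
  meta0 <- acquisition_meta(350, 70, uptake_time_min = 0)
  conc <- 350e6 / 70000
  v1 <- scalar_volume(array(conc, c(2, 2, 2)), c(1, 1, 1),
                      units = "ACTIVITY_BQ_ML")
  expect_equal(to_suv(v1, meta0)$data, array(1, c(2, 2, 2)))

  # doubling injected activity halves every SUV
  meta2 <- acquisition_meta(700, 70, uptake_time_min = 109.77)
  expect_equal(to_suv(v, meta2)$data, s$data / 2)

  expect_error(to_suv(scalar_volume(array(1, c(2, 2, 2)), c(1, 1, 1)), meta),
               "ACTIVITY_BQ_ML")
})

test_that("VOI extraction returns foreground values in stable order", {
  arr <- array(seq_len(24), c(4, 3, 2))
  vol <- make_vol(arr)
  m <- array(0L, c(4, 3, 2)); m[c(1, 7, 20)] <- 1L
  voi <- extract_voi(vol, voi_mask(m, c(1, 1, 1)))
  expect_equal(voi$values, c(1, 7, 20))
  full <- extract_voi(vol, make_mask_full(c(4, 3, 2)))
  expect_equal(full$values, as.numeric(1:24))
  const <- extract_voi(make_vol(array(5, c(4, 3, 2))),
                       make_mask_full(c(4, 3, 2)))
  expect_true(all(const$values == 5))
  expect_error(extract_voi(vol, voi_mask(array(0L, c(4, 3, 2)), c(1, 1, 1))),
               "empty")
  expect_error(extract_voi(vol, make_mask_full(c(2, 2, 2))), "congruent")
})

test_that("quantization follows the floor formula with clamped maximum", {
  expect_equal(quantize(c(0, 1, 2, 3), 4)$bin, 1:4)
  expect_equal(quantize(c(0, 0.5, 1), 2)$bin, c(1L, 2L, 2L))
  expect_equal(quantize(rep(7, 5), 64)$bin, rep(1L, 5))
  q <- quantize(runif(100), 64)
  expect_true(all(q$bin >= 1 & q$bin <= 64))
  expect_equal(length(q$edges), 65)
})

test_that("quantization is invariant to increasing affine rescaling and
           occupied bins contain a raw value in their edge interval", {
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(200)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_identical(quantize(v, 64)$bin, quantize(a * v + b, 64)$bin)
  }
  v <- rnorm(500)
  q <- quantize(v, 64)
  for (bin in unique(q$bin)) {
    lo <- q$edges[bin]; hi <- q$edges[bin + 1]
    inside <- if (bin == 64) v >= lo & v <= hi else v >= lo & v < hi + 1e-12
    expect_true(any(inside[q$bin == bin]))
  }
})

test_that("Gaussian FWHM filter preserves constants, mass and matches the
           closed-form impulse response", {
  cv <- make_vol(array(3.5, c(8, 8, 8)), spacing = c(2, 2, 2))
  sm <- gaussian_fwhm_filter(cv, 6)
  expect_equal(sm$data, cv$data, tolerance = 1e-12)

  set.seed(5)
  rv <- make_vol(array(rnorm(10^3), c(10, 10, 10)), spacing = c(4.7, 4.7, 3.27))
  sm2 <- gaussian_fwhm_filter(rv, 6)
  expect_equal(sum(sm2$data), sum(rv$data), tolerance = 1e-6)

  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  iv <- make_vol(imp, spacing = c(2, 2, 2))
  r <- gaussian_fwhm_filter(iv, 6)$data
  sig_vox <- (6 / (2 * sqrt(2 * log(2)))) / 2
  k1 <- exp(-(-7:7)^2 / (2 * sig_vox^2)); k1 <- k1 / sum(k1)
  along <- r[, 8, 8] / r[8, 8, 8]
  expect_equal(along, k1 / max(k1), tolerance = 1e-6)
})

test_that("LoG filter kills constants, ignores DC shifts and peaks at an
           impulse centre", {
  cv <- make_vol(array(2, c(8, 8, 6)), spacing = c(2, 2, 2))
  expect_equal(log_filter(cv, 3)$data, array(0, c(8, 8, 6)),
               tolerance = 1e-12)

  set.seed(6)
  f <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  r1 <- log_filter(make_vol(f, spacing = c(2, 2, 2)), 3)$data
  r2 <- log_filter(make_vol(f + 17, spacing = c(2, 2, 2)), 3)$data
  expect_equal(r1, r2, tolerance = 1e-9)

  # impulse response: maximal magnitude at the centre, negative there
  # (second derivative of a peak), matching the analytic 1D LoG profile
  imp <- array(0, c(17, 17, 17)); imp[9, 9, 9] <- 1
  r <- log_filter(make_vol(imp, spacing = c(1, 1, 1)), 2)$data
  expect_equal(which.max(abs(r)), which(imp == 1))
  expect_lt(r[9, 9, 9], 0)
  # analytic LoG along an axis: (g''(x) g(0) g(0) + 2 g(x) g''(0) terms)
  sig <- 2
  g <- function(x) exp(-x^2 / (2 * sig^2))
  gn <- function(x) g(x) / sum(g(-8:8))
  d2 <- function(x) gn(x) * (x^2 - sig^2) / sig^4
  x <- -8:8
  analytic <- d2(x) * gn(0) * gn(0) + 2 * gn(x) * d2(0) * gn(0)
  profile <- r[, 9, 9]
  # compare shape up to the common discrete-kernel DC correction
  expect_gt(cor(profile, analytic), 0.999)

  expect_error(log_filter(make_vol(array(1, c(4, 4, 4)),
                                   spacing = c(20, 20, 20)), 1),
               "0.1 voxel")
})
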