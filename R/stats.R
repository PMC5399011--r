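#' Paired Wilcoxon signed-rank test
#'
#' Two-sided related-samples signed-rank test. Zero differences are
#' discarded (classical handling; `zeros = "pratt"` keeps them in the
#' ranking but excludes them from the statistic). Ties among absolute
#' differences are mid-ranked. The p value is exact (signed-rank
#' distribution) when `n <= exact_max` and the data are tie-free, and
#' otherwise uses the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param early,late paired numeric vectors of equal length.
#' @param exact_max largest n for the exact branch (default 25).
#' @param zeros `"discard"` (default) or `"pratt"`.
#' @return List with `statistic` (V, sum of positive ranks), `p`, `n`
#'   (pairs used), `method`, and `flags`.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 1)$p # 2/64
#' @export
wilcoxon_signed_rank <- function(early, late, exact_max = 25,
                                 zeros = c("discard", "pratt")) {
  zeros <- match.arg(zeros)
  stopifnot(length(early) == length(late))
  ok <- is.finite(early) & is.finite(late)
  d <- late[ok] - early[ok]
  flags <- character(0)
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate",
                flags = "all_differences_zero"))
  }
  if (zeros == "discard") {
    d_used <- d[nz]
    r <- rank(abs(d_used))
  } else {
    r_all <- rank(abs(d))
    d_used <- d[nz]
    r <- r_all[nz]
  }
  n <- length(d_used)
  if (n < 5) stop("wilcoxon_signed_rank: fewer than 5 nonzero differences",
                  call. = FALSE)
  v <- sum(r[d_used > 0])
  ties <- any(duplicated(abs(d_used))) || (zeros == "pratt" && any(!nz))
  if (n <= exact_max && !ties) {
    p <- 2 * min(psignrank(v, n), psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      return(list(statistic = v, p = 1, n = n, method = "degenerate",
                  flags = c(flags, "zero_variance_ranks")))
    }
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
    if (ties) flags <- c(flags, "ties_present")
  }
  list(statistic = v, p = p, n = as.integer(n), method = method,
       flags = flags)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; two-sided p via the t
#' approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return List with `r`, `p`, `n`, `flags`.
#' @export
spearman_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_rank: need at least 4 complete pairs",
                  call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n,
                flags = "zero_rank_variance"))
  }
  r <- cor(rx, ry)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n, flags = character(0))
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure ICC(2,1) from the standard mean-squares
#' decomposition of a subjects x raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters).
#' @return List with `icc`, `n_subjects`, `n_raters`, `flags`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 5, k >= 2, all(is.finite(ratings)))
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  flags <- character(0)
  if (msr <= 0) flags <- "zero_between_subject_variance"
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) {
    flags <- c(flags, "degenerate_denominator")
    NA_real_
  } else {
    (msr - mse) / denom
  }
  list(icc = icc, n_subjects = n, n_raters = k, flags = flags)
}
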