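#' Median and interquartile range
#'
#' The IQR is reported as the single width Q3 - Q1, with quartiles by
#' linear interpolation (R's default type-7 rule), matching the one-number
#' IQR columns of routine lipid reports.
#'
#' @param values numeric vector, `n >= 1`; `NA`s removed with a warning-free
#'   drop.
#' @return List with `median`, `iqr`, `q1`, `q3`, `n`.
#' @examples
#' median_iqr(c(1, 2, 3, 4))
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("median_iqr: empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], iqr = q[3L] - q[1L], q1 = q[1L], q3 = q[3L],
       n = length(values))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired two-sided test of median difference zero. Zero differences are
#' dropped (Wilcoxon's rule), absolute differences are mid-ranked, and the
#' statistic is the sum of ranks of positive differences (`V`). The p-value
#' uses the normal approximation with the tie correction and no continuity
#' correction, so it matches `stats::wilcox.test(..., exact = FALSE,
#' correct = FALSE)` exactly; that stock routine serves as the package's
#' independent oracle in the test suite.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return List with `statistic` (V, sum of positive ranks), `z`, `p`
#'   (two-sided) and `n` (nonzero differences used).
#' @examples
#' wilcoxon_signed_rank(1:10, (1:10) + rnorm(10))
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    stop("degenerate test: zero variance of the signed-rank statistic",
         call. = FALSE)
  }
  z <- (v - mu) / sqrt(sigma2)
  list(statistic = v, z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties share the average rank. Undefined
#' (error) when either vector is constant.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("spearman_rho: need n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(rank(x), rank(y))
}

#' Bland-Altman limits of agreement
#'
#' For paired estimates, differences `d = a - b` and means `m = (a + b)/2`;
#' bias is `mean(d)`, the 95% limits of agreement are
#' `bias +/- 1.96 * sd(d)` (sample sd, n-1 denominator; the 1.96 multiplier
#' is fixed by convention). The per-pair `(mean, difference)` series is
#' returned for plotting or export.
#'
#' @param a,b paired numeric vectors, both present per pair, `n >= 2`.
#' @return A list of class `"bland_altman"`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pct_within_loa`, `n`, and `series` (data.frame with
#'   `mean`, `diff`).
#' @examples
#' bland_altman(c(1.4, 2.5, 3.6), c(1.0, 2.0, 3.0))
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("bland_altman: need at least 2 complete pairs",
                   call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  structure(list(bias = bias, sd_diff = sd_diff, loa_low = loa_low,
                 loa_high = loa_high,
                 pct_within_loa = 100 * mean(d >= loa_low & d <= loa_high),
                 n = n, series = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, sd %.4f, LoA [%.4f, %.4f], %.1f%% within\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high,
              x$pct_within_loa))
  invisible(x)
}

#' Plot a Bland-Altman object
#'
#' Minimal base-graphics rendering: the (mean, difference) scatter with the
#' bias and both limits as horizontal lines. Numeric CSV export (see
#' [write_report()]) is the contract; the plot is a convenience.
#'
#' @param x a [bland_altman()] result.
#' @param ... passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$series$mean, x$series$diff,
       xlab = "Mean of pair", ylab = "Difference (a - b)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Thin wrappers for cohort descriptives
#'
#' The analysis path is nonparametric throughout (medians, signed-rank);
#' these wrappers expose the conventional normality and two-group tests as
#' pipeline diagnostics only. `ks_normality` is the one-sample
#' Kolmogorov-Smirnov test against a normal with the sample's own moments
#' (a diagnostic, not a calibrated test); `mann_whitney_u` and
#' `t_test_means` wrap the stock two-sample tests.
#'
#' @param x,y numeric vectors.
#' @return The underlying `htest` object.
#' @name cohort-descriptive-tests
NULL

#' @rdname cohort-descriptive-tests
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
}

#' @rdname cohort-descriptive-tests
#' @export
mann_whitney_u <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
}

#' @rdname cohort-descriptive-tests
#' @export
t_test_means <- function(x, y) stats::t.test(x, y)
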