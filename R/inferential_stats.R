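#' Group summary for two-sample tests
#'
#' @param n sample size (>= 2).
#' @param mean sample mean.
#' @param sd sample standard deviation (divisor n - 1), >= 0.
#' @return A `summary_group` list.
#' @export
summary_group <- function(n, mean, sd) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_group")
}

as_summary_group <- function(x) {
  if (inherits(x, "summary_group")) return(x)
  if (is.numeric(x) && length(x) > 1L)
    return(summary_group(length(x), mean(x), stats::sd(x)))
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x)))
    return(summary_group(x$n, x$mean, x$sd))
  stop("cannot interpret input as a group: supply a raw numeric vector, ",
       "a summary_group, or a list(n, mean, sd)")
}

stat_result <- function(statistic, df, p, estimate = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), estimate = estimate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("statistic = %.4f, df = (%s), p = %.4g\n",
              x$statistic, dfs, x$p))
  if (!is.null(x$estimate))
    cat(sprintf("estimate = %.4f\n", x$estimate))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' The equal-variance two-sample t statistic with df = n1 + n2 - 2,
#' computable either from raw vectors or from their (n, mean, sd)
#' summaries — the two routes agree exactly, which lets published group
#' summary tables be re-tested without the raw data.
#'
#' @param g1,g2 numeric vectors, `summary_group` objects, or
#'   `list(n, mean, sd)`.
#' @return A `stat_result` with `statistic`, `df`, two-sided `p`.
#' @export
#' @examples
#' pooled_t(summary_group(20, 104.25, 24.92), summary_group(17, 18.41, 11.57))
pooled_t <- function(g1, g2) {
  g1 <- as_summary_group(g1)
  g2 <- as_summary_group(g2)
  if (g1$sd == 0 && g2$sd == 0) stop("both groups have zero SD")
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  stat_result(t, df, 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' Pearson's chi-square without continuity correction on a contingency
#' table of counts, df = (rows - 1)(cols - 1).
#'
#' @param counts matrix of non-negative integer counts with positive row
#'   and column sums.
#' @return A `stat_result`.
#' @export
#' @examples
#' chi_square(rbind(c(15, 3, 2), c(14, 1, 2)))  # handedness-style 2 x 3 table
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  stat_result(res$statistic, res$parameter, res$p.value)
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value. Swapping the two correlations negates Z.
#'
#' @param r1,r2 correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, each > 3.
#' @return A `stat_result`.
#' @export
#' @examples
#' fisher_z_compare(0.46, 20, -0.32, 17)
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat_result(z, Inf, 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `stat_result` with `estimate` = r and df = n - 2.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  res <- stats::cor.test(x, y, method = "pearson")
  stat_result(res$statistic, res$parameter, res$p.value,
              estimate = unname(res$estimate))
}

#' Variance-ratio F test from group summaries
#'
#' `F = sd1^2 / sd2^2` on (n1 - 1, n2 - 1) degrees of freedom with a
#' two-sided p-value; the standard ratio-of-sample-variances test.
#'
#' @param g1,g2 numeric vectors, `summary_group` objects, or
#'   `list(n, mean, sd)`; both SDs must be positive.
#' @return A `stat_result`.
#' @export
variance_ratio <- function(g1, g2) {
  g1 <- as_summary_group(g1)
  g2 <- as_summary_group(g2)
  if (g1$sd <= 0 || g2$sd <= 0) stop("both SDs must be positive")
  f <- g1$sd^2 / g2$sd^2
  df <- c(g1$n - 1L, g2$n - 1L)
  p <- 2 * min(stats::pf(f, df[1], df[2]),
               stats::pf(f, df[1], df[2], lower.tail = FALSE))
  stat_result(f, df, min(p, 1))
}
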