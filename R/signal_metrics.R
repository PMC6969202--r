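#' Region-of-interest time-series container
#'
#' Bundles one subject's T x R matrix of BOLD amplitudes with its ROI labels,
#' subject identifier and group label. Columns are regions, rows are time
#' points (TRs). All metric functions in the package operate on this
#' container or on single numeric series extracted from it.
#'
#' @param data numeric T x R matrix (or data.frame coercible to one); rows
#'   are time points, columns are regions. Must be finite with no missing
#'   values and have at least 3 rows.
#' @param subject_id character scalar identifying the subject.
#' @param group character scalar group label (e.g. `"ASD"`, `"TD"`).
#' @param roi_labels character vector of region names; defaults to the
#'   column names of `data`.
#'
#' @return An object of class `roi_ts`: the data matrix with `subject_id`
#'   and `group` attributes and ROI labels as column names.
#' @export
#' @examples
#' ts <- roi_ts(matrix(rnorm(60), 20, 3), "sub-01", "TD")
roi_ts <- function(data, subject_id, group = NA_character_, roi_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 3L)
    stop("time series must have at least 3 time points, got ", nrow(data))
  if (anyNA(data) || !all(is.finite(data)))
    stop("time series contains missing or non-finite values")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data)
    if (is.null(roi_labels))
      roi_labels <- sprintf("roi%03d", seq_len(ncol(data)))
  }
  if (length(roi_labels) != ncol(data))
    stop("roi_labels length (", length(roi_labels),
         ") does not match number of columns (", ncol(data), ")")
  colnames(data) <- roi_labels
  structure(data,
            subject_id = as.character(subject_id),
            group = as.character(group),
            class = c("roi_ts", "matrix", "array"))
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s (group %s): %d time points x %d ROIs\n",
              attr(x, "subject_id"), attr(x, "group"), nrow(x), ncol(x)))
  invisible(x)
}

#' Z-normalize ROI time series
#'
#' Rescales every column to sample mean 0 and sample standard deviation 1
#' (divisor n - 1). Variability and complexity metrics are computed on the
#' normalized series so that amplitude units cancel and the entropy
#' tolerance (a fraction of the SD) becomes an absolute tolerance.
#'
#' @param series a [roi_ts] object, or a plain numeric matrix.
#' @return An object of the same shape with each column standardized.
#' @export
znormalize <- function(series) {
  x <- as.matrix(series)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("cannot z-normalize constant ROI column(s): ",
         paste(bad, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (inherits(series, "roi_ts")) {
    out <- roi_ts(out, attr(series, "subject_id"), attr(series, "group"),
                  colnames(x))
  }
  out
}

#' Mean square successive difference (MSSD)
#'
#' The average of squared differences between consecutive time points,
#' `sum((x[i+1] - x[i])^2) / (n - 1)` for a series of length `n`. MSSD
#' measures moment-to-moment variability and, unlike the variance, is
#' insensitive to slow drifts in the mean.
#'
#' For a z-scored stationary AR(1) process with lag-1 coefficient `phi` the
#' population value is `2 * (1 - phi)`, which the synthetic-data generator
#' exploits as an analytic check.
#'
#' @param x numeric vector, length >= 3.
#' @return Non-negative scalar; 0 if and only if the series is constant.
#' @export
#' @examples
#' mssd(c(0, 1, 3, 2, 5))  # 15/4
mssd <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("mssd needs at least 3 time points, got ", n)
  if (anyNA(x)) stop("mssd input contains missing values")
  sum(diff(x)^2) / (n - 1)
}

#' Sample standard deviation of a series
#'
#' Retained as a comparison metric for MSSD (unlike MSSD it is sensitive to
#' mean drifts, and empirically more contaminated by head motion). Sample
#' convention, divisor n - 1.
#'
#' @param x numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
sd_metric <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("sd_metric needs at least 2 time points")
  stats::sd(x)
}

#' Sample entropy of a single time series
#'
#' Sample entropy (SampEn) quantifies signal complexity as `-log(A/B)`,
#' where `B` counts pairs of length-`m` templates whose Chebyshev distance
#' is at most r times the series SD and `A` counts the same pairs still matching when
#' the templates are extended to length `m + 1`. Self-matches are excluded
#' and each unordered pair is counted once; templates of both lengths start
#' at positions `1..(n - m)` so the two counts range over the same pairs.
#' Values are low for strongly deterministic and for purely random signals
#' and high for complex ones.
#'
#' When no template pairs match at either length (`A == 0` or `B == 0`) the
#' entropy is undefined. This is an estimation *failure*, signalled by
#' `NA_real_` rather than an error, because the parameter-calibration grid
#' counts failures across many voxels rather than aborting on the first.
#'
#' @param x numeric vector, length >= m + 2.
#' @param m integer pattern length (number of samples matched), >= 1.
#' @param r tolerance factor in (0, 1), as a fraction of the series'
#'   standard deviation (divisor n - 1).
#' @return Scalar entropy, or `NA_real_` on estimation failure.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(180), m = 2, r = 0.5)
#' sample_entropy(1:10, m = 2, r = 0.05)  # monotone ramp: failure (NA)
sample_entropy <- function(x, m, r) {
  x <- as.numeric(x)
  n <- length(x)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m != round(m))
    stop("m must be a positive integer")
  m <- as.integer(m)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("r must be a positive tolerance factor")
  if (n < m + 2L)
    stop("series too short for sample entropy: need n >= m + 2 (n = ",
         n, ", m = ", m, ")")
  if (anyNA(x)) stop("sample_entropy input contains missing values")
  tol <- r * stats::sd(x)
  ab <- sampen_counts(x, m, tol)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Compute a per-ROI metric for a set of subjects
#'
#' Applies one of the signal metrics column-wise to every subject's
#' (z-normalized) time series, returning a subjects x ROI matrix in the
#' order of `dataset`. Entropy estimation failures propagate as `NA` cells
#' with a warning.
#'
#' @param dataset list of [roi_ts] objects sharing identical `roi_labels`.
#' @param metric one of `"mssd"`, `"sd"`, `"sampen"`.
#' @param m,r sample-entropy parameters, required for `metric = "sampen"`.
#' @param normalize z-normalize each series first (default `TRUE`, the
#'   standard preparation).
#' @return Numeric matrix, rows named by subject id, columns by ROI.
#' @export
metric_matrix <- function(dataset, metric = c("mssd", "sd", "sampen"),
                          m = NULL, r = NULL, normalize = TRUE) {
  metric <- match.arg(metric)
  if (length(dataset) == 0L) stop("empty dataset")
  labels <- colnames(dataset[[1L]])
  for (s in dataset) {
    if (!identical(colnames(s), labels))
      stop("ROI labels differ across subjects (subject ",
           attr(s, "subject_id"), ")")
  }
  if (metric == "sampen" && (is.null(m) || is.null(r)))
    stop("metric 'sampen' requires m and r")
  fn <- switch(metric,
               mssd = mssd,
               sd = sd_metric,
               sampen = function(x) sample_entropy(x, m, r))
  out <- t(vapply(dataset, function(s) {
    xs <- if (normalize) znormalize(s) else s
    apply(as.matrix(xs), 2, fn)
  }, numeric(length(labels))))
  dimnames(out) <- list(vapply(dataset, attr, "", "subject_id"), labels)
  nfail <- sum(is.na(out))
  if (nfail > 0)
    warning(nfail, " entropy estimation failure(s) propagated as NA cells")
  out
}
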