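#' Standard error of sample entropy over noise-reference voxels
#'
#' For one subject's set of CSF (noise-reference) voxel time courses,
#' computes sample entropy per voxel at the given `(m, r)` and summarizes
#' the estimate's stability as
#' `SE = 1.96 * (sd(entropies) / mean(entropies))^2`,
#' i.e. 1.96 times the squared coefficient of variation across voxels.
#' Failed voxels (no template matches) are excluded from the mean/SD and
#' counted separately. The squared form is dimensionally unusual but is the
#' published convention this calibration follows; `squared = FALSE` gives
#' the plain coefficient-of-variation variant.
#'
#' @param voxels numeric V x T matrix, one row per reference voxel.
#' @param m,r sample-entropy parameters (see [sample_entropy()]).
#' @param squared use the squared coefficient of variation (default).
#' @return List with `se` (scalar, `NA` if undefined), `n_failures`
#'   (voxels with estimation failure), `mean_entropy`, `sd_entropy`.
#' @export
entropy_se <- function(voxels, m, r, squared = TRUE) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) < 2L) stop("need at least 2 reference voxels")
  ent <- apply(voxels, 1, function(v) sample_entropy(v, m, r))
  fails <- sum(is.na(ent))
  ok <- ent[!is.na(ent)]
  if (length(ok) < 2L)
    return(list(se = NA_real_, n_failures = fails,
                mean_entropy = NA_real_, sd_entropy = NA_real_))
  mu <- mean(ok)
  sigma <- stats::sd(ok)
  se <- if (mu == 0) NA_real_ else {
    cv <- sigma / mu
    1.96 * (if (squared) cv^2 else cv)
  }
  list(se = se, n_failures = fails, mean_entropy = mu, sd_entropy = sigma)
}

#' Calibrate sample-entropy parameters on noise-reference voxels
#'
#' Evaluates every combination of pattern length `m` and tolerance `r` on
#' each subject's CSF voxel set. Per cell, the median of the per-subject
#' standard errors (see [entropy_se()]) and the total count of estimation
#' failures over all voxels and subjects are recorded. A combination is
#' *acceptable* when the median SE is below `se_threshold` and there are
#' zero estimation failures. A cell whose SE is undefined for any subject
#' (degenerate reference signal, mean entropy zero) is never acceptable.
#'
#' The default grid is m = 1..4 and r = 0.05..0.80 in steps of 0.05.
#'
#' @param csf_sets named list (one element per subject) of V x T numeric
#'   matrices of noise-reference time courses.
#' @param m_values,r_values parameter grids; must be non-empty.
#' @param se_threshold acceptability threshold on the median SE (default 0.1).
#' @param squared passed to [entropy_se()].
#' @return A data.frame of class `entropy_grid` in long format with columns
#'   `m`, `r`, `median_se`, `n_failures`, `acceptable`, plus a
#'   `per_subject_se` attribute (cells x subjects matrix).
#' @export
calibrate_entropy_grid <- function(csf_sets,
                                   m_values = 1:4,
                                   r_values = seq(0.05, 0.80, by = 0.05),
                                   se_threshold = 0.1,
                                   squared = TRUE) {
  if (length(csf_sets) < 1L) stop("need at least one subject")
  if (length(m_values) == 0L || length(r_values) == 0L)
    stop("m_values and r_values must be non-empty")
  grid <- expand.grid(r = r_values, m = m_values)[, c("m", "r")]
  nsub <- length(csf_sets)
  se_mat <- matrix(NA_real_, nrow(grid), nsub)
  colnames(se_mat) <- names(csf_sets)
  fails <- integer(nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    for (s in seq_len(nsub)) {
      res <- entropy_se(csf_sets[[s]], grid$m[cell], grid$r[cell],
                        squared = squared)
      se_mat[cell, s] <- res$se
      fails[cell] <- fails[cell] + res$n_failures
    }
  }
  med <- apply(se_mat, 1, function(v) {
    if (anyNA(v)) NA_real_ else stats::median(v)
  })
  out <- data.frame(m = grid$m, r = grid$r, median_se = med,
                    n_failures = fails,
                    acceptable = !is.na(med) & med < se_threshold & fails == 0L)
  attr(out, "per_subject_se") <- se_mat
  attr(out, "se_threshold") <- se_threshold
  class(out) <- c("entropy_grid", "data.frame")
  out
}

#' @export
print.entropy_grid <- function(x, ...) {
  cat(sprintf(
    "<entropy_grid> %d (m, r) cells, %d acceptable (median SE < %g, 0 failures)\n",
    nrow(x), sum(x$acceptable), attr(x, "se_threshold")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Acceptable (m, r) conditions of a calibration grid
#'
#' @param grid an `entropy_grid` from [calibrate_entropy_grid()].
#' @param m restrict to one pattern length (optional).
#' @param exclude_r tolerance values to drop even if acceptable; the shipped
#'   study default averages the m = 2 conditions but excludes r = 0.20,
#'   which contrasts with the other tolerances.
#' @return Data.frame with columns `m`, `r`.
#' @export
acceptable_conditions <- function(grid, m = NULL, exclude_r = numeric()) {
  sel <- grid[grid$acceptable, c("m", "r")]
  if (!is.null(m)) sel <- sel[sel$m == m, ]
  if (length(exclude_r))
    sel <- sel[!vapply(sel$r, function(r) any(abs(r - exclude_r) < 1e-9),
                       logical(1)), ]
  rownames(sel) <- NULL
  sel
}

#' Average entropy over selected (m, r) conditions
#'
#' Cell-wise arithmetic mean of a subjects x ROI x conditions entropy array
#' over a chosen set of conditions. Failed (NA) cells are excluded from
#' that cell's mean pairwise rather than dropping the subject; the count of
#' such exclusions is reported as a warning and attribute.
#'
#' @param entropy_array 3-d numeric array, subjects x ROIs x conditions,
#'   with condition dimnames of the form `"m2_r0.25"` (as produced by
#'   [entropy_condition_array()]).
#' @param selected data.frame with columns `m`, `r` naming the conditions
#'   to average (e.g. from [acceptable_conditions()]).
#' @param grid optional `entropy_grid`; when supplied, selecting a
#'   condition the grid does not flag acceptable is an error unless
#'   `allow_unacceptable = TRUE`.
#' @param allow_unacceptable override the acceptability check.
#' @return Subjects x ROI matrix of condition-averaged entropy.
#' @export
average_over_conditions <- function(entropy_array, selected, grid = NULL,
                                    allow_unacceptable = FALSE) {
  if (nrow(selected) == 0L) stop("empty condition selection")
  keys <- condition_key(selected$m, selected$r)
  have <- dimnames(entropy_array)[[3]]
  missing_keys <- setdiff(keys, have)
  if (length(missing_keys))
    stop("conditions not present in entropy array: ",
         paste(missing_keys, collapse = ", "))
  if (!is.null(grid) && !allow_unacceptable) {
    ok <- condition_key(grid$m[grid$acceptable], grid$r[grid$acceptable])
    bad <- setdiff(keys, ok)
    if (length(bad))
      stop("selected condition(s) not flagged acceptable: ",
           paste(bad, collapse = ", "),
           " (set allow_unacceptable = TRUE to override)")
  }
  sub <- entropy_array[, , keys, drop = FALSE]
  n_na <- sum(is.na(sub))
  out <- apply(sub, c(1, 2), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  if (n_na > 0)
    warning(n_na, " failed cell(s) excluded pairwise from condition averaging")
  attr(out, "n_excluded") <- n_na
  out
}

condition_key <- function(m, r) sprintf("m%d_r%.2f", as.integer(m), r)

#' Entropy matrices for a set of (m, r) conditions
#'
#' Convenience wrapper building the subjects x ROI x conditions array that
#' [average_over_conditions()] consumes, by calling [metric_matrix()] once
#' per condition.
#'
#' @param dataset list of [roi_ts] objects.
#' @param conditions data.frame with columns `m`, `r`.
#' @param normalize z-normalize series first (default `TRUE`).
#' @return 3-d array with condition keys (`"m2_r0.25"`) on the third axis.
#' @export
entropy_condition_array <- function(dataset, conditions, normalize = TRUE) {
  if (nrow(conditions) == 0L) stop("no conditions supplied")
  mats <- lapply(seq_len(nrow(conditions)), function(i)
    suppressWarnings(
      metric_matrix(dataset, "sampen", m = conditions$m[i],
                    r = conditions$r[i], normalize = normalize)))
  arr <- array(unlist(mats),
               dim = c(dim(mats[[1]]), nrow(conditions)),
               dimnames = c(dimnames(mats[[1]]),
                            list(condition_key(conditions$m, conditions$r))))
  arr
}

#' Default condition selection used for study averaging
#'
#' The calibration in the accompanying analyses accepts all m = 2
#' tolerances from 0.20 to 0.65; averaging then drops r = 0.20 because its
#' entropy estimates contrast with the remaining tolerances. This helper
#' encodes that default: m = 2, r in 0.25..0.65 (step 0.05).
#'
#' @return Data.frame with columns `m`, `r`.
#' @export
default_entropy_conditions <- function() {
  data.frame(m = 2L, r = seq(0.25, 0.65, by = 0.05))
}
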