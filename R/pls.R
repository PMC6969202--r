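## Partial least squares for brain-behavior analysis.
##
## Two flavours are implemented, both as SVDs of a cross-block matrix:
##   mean-centering PLS  — SVD of the column-centered matrix of group (or
##                         condition) means of the brain variables; extracts
##                         the group contrasts that best explain them.
##   behavioral PLS      — SVD of the stacked per-group behavior x brain
##                         Pearson correlation matrix; extracts the patterns
##                         of maximal brain-behavior covariance.
## Inference is nonparametric: permutation of subject rows for latent-
## variable significance, stratified bootstrap for salience reliability
## (bootstrap ratios, BSR).

# SVD with deterministic sign convention: per LV the largest-magnitude
# element of the right (brain) singular vector is made positive.
fixed_sign_svd <- function(M) {
  s <- svd(M)
  for (k in seq_along(s$d)) {
    i <- which.max(abs(s$v[, k]))
    if (s$v[i, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  s
}

check_columns_vary <- function(mat, what) {
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(mat)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ", what, " column(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Stacked per-group correlation matrix (groups x behaviors rows, brain cols).
cross_correlation <- function(X, Y, groups) {
  lv <- levels(groups)
  blocks <- lapply(lv, function(g) {
    idx <- groups == g
    stats::cor(Y[idx, , drop = FALSE], X[idx, , drop = FALSE])
  })
  M <- do.call(rbind, blocks)
  rownames(M) <- as.vector(t(outer(lv, colnames(Y), paste, sep = ".")))
  M
}

new_bbpls <- function(method, cross, s, extra) {
  k <- length(s$d)
  out <- c(list(
    method = method,
    cross = cross,
    singular_values = s$d,
    cov_explained = s$d^2 / sum(s$d^2),
    brain_saliences = structure(s$v,
                                dimnames = list(colnames(cross),
                                                paste0("LV", seq_len(k)))),
    u = structure(s$u, dimnames = list(rownames(cross),
                                       paste0("LV", seq_len(k))))),
    extra)
  class(out) <- "bbpls"
  out
}

#' Mean-centering PLS: group/condition contrasts in brain variables
#'
#' Builds the groups x brain-variables matrix of group means, removes the
#' grand mean of the group means from each column, and decomposes the
#' result by SVD. Left singular vectors are design saliences (the group
#' contrasts), right singular vectors are brain saliences; singular values
#' measure the covariance each latent variable (LV) captures.
#'
#' @param X numeric subjects x brain-variables matrix (no missing cells).
#' @param groups factor (or coercible) of group/condition labels, one per
#'   row of `X`; every level needs at least one row (two for inference).
#' @param n_perm permutations for LV significance (0 to skip).
#' @param n_boot stratified bootstrap samples for salience reliability
#'   (0 to skip).
#' @param seed integer seed controlling permutation and bootstrap draws.
#' @param ... passed on to [pls_permutation()] and [pls_bootstrap()].
#' @return An object of class `bbpls`; see [behavioral_pls()] for the
#'   common fields. `design_saliences` holds the group contrasts and
#'   `brain_scores = X %*% brain_saliences`.
#' @export
mean_centering_pls <- function(X, groups, n_perm = 1000, n_boot = 500,
                               seed = NULL, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(X)) stop("groups length must match rows of X")
  if (nlevels(groups) < 2L) stop("need at least 2 groups/conditions")
  if (any(table(groups) < 1L)) stop("every group needs at least one row")
  if (anyNA(X)) stop("X contains missing cells")
  G <- apply(X, 2, function(col) tapply(col, groups, mean))
  M <- sweep(G, 2, colMeans(G))  # grand mean of group means removed
  s <- fixed_sign_svd(M)
  fit <- new_bbpls("meancentering", M, s, list(
    X = X, groups = groups,
    design_saliences = structure(s$u,
                                 dimnames = list(levels(groups),
                                                 paste0("LV", seq_along(s$d)))),
    brain_scores = X %*% s$v,
    seed = seed))
  colnames(fit$brain_scores) <- paste0("LV", seq_along(s$d))
  if (n_perm > 0) fit <- pls_permutation(fit, n_perm = n_perm, seed = seed, ...)
  if (n_boot > 0) fit <- pls_bootstrap(fit, n_boot = n_boot, seed = seed, ...)
  fit
}

#' Behavioral PLS: brain-behavior covariance patterns
#'
#' For each group, the behavior-variables x brain-variables Pearson
#' correlation matrix is computed; the per-group matrices are stacked
#' row-wise and decomposed by SVD. Right singular vectors are brain
#' saliences (one weight per brain variable per LV); the left singular
#' vectors, in per-group blocks, are behavior saliences. Brain scores are
#' `X %*% brain_saliences`; behavior scores project each subject's
#' (normalized) behavior row onto their group's behavior-salience block.
#'
#' Behavior variables are z-normalized (mean 0, SD 1) before analysis
#' unless `normalize_Y = FALSE`. Pairs of behavior variables correlated
#' above |r| = 0.8 trigger a collinearity warning, since strongly redundant
#' behavior columns bias the decomposition.
#'
#' @param X numeric subjects x brain-variables matrix.
#' @param Y numeric subjects x behavior-variables matrix or data.frame.
#' @param groups factor of group labels, one per subject; a single group is
#'   allowed (pass `NULL` or a constant).
#' @param n_perm,n_boot,seed,... see [mean_centering_pls()].
#' @param normalize_Y z-score behavior columns first (default `TRUE`).
#' @return Object of class `bbpls` with fields `singular_values`,
#'   `cov_explained` (fractions summing to 1), `brain_saliences`,
#'   `behavior_saliences` (rows `group.variable`), `brain_scores`,
#'   `behavior_scores`, and — after inference — `perm` (`p`, `n_perm`,
#'   permuted singular values) and `boot` (`bsr`, bootstrap SEs, percentile
#'   CIs for behavior saliences, `reliable` flags at `bsr_threshold`).
#' @export
behavioral_pls <- function(X, Y, groups = NULL, n_perm = 1000, n_boot = 500,
                           seed = NULL, normalize_Y = TRUE, ...) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%02d", seq_len(ncol(Y)))
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same subjects (rows)")
  if (is.null(groups)) groups <- rep("all", nrow(X))
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(X)) stop("groups length must match rows of X")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 subjects")
  if (anyNA(X) || anyNA(Y)) stop("missing cells in X or Y")
  check_columns_vary(X, "brain")
  check_columns_vary(Y, "behavior")
  if (normalize_Y) Y <- scale(Y)
  if (ncol(Y) > 1L) {
    ycor <- stats::cor(Y)
    high <- abs(ycor[upper.tri(ycor)]) > 0.8
    if (any(high))
      warning(sum(high), " behavior-variable pair(s) with |r| > 0.8; ",
              "collinear behaviors can bias the decomposition")
  }
  M <- cross_correlation(X, Y, groups)
  s <- fixed_sign_svd(M)
  k <- length(s$d)
  behavior_scores <- matrix(NA_real_, nrow(Y), k)
  b <- ncol(Y)
  for (gi in seq_len(nlevels(groups))) {
    idx <- groups == levels(groups)[gi]
    block <- s$u[(gi - 1L) * b + seq_len(b), , drop = FALSE]
    behavior_scores[idx, ] <- Y[idx, , drop = FALSE] %*% block
  }
  colnames(behavior_scores) <- paste0("LV", seq_len(k))
  fit <- new_bbpls("behavioral", M, s, list(
    X = X, Y = Y, groups = groups,
    behavior_saliences = structure(s$u,
                                   dimnames = list(rownames(M),
                                                   paste0("LV", seq_len(k)))),
    brain_scores = structure(X %*% s$v,
                             dimnames = list(rownames(X),
                                             paste0("LV", seq_len(k)))),
    behavior_scores = behavior_scores,
    seed = seed))
  if (n_perm > 0) fit <- pls_permutation(fit, n_perm = n_perm, seed = seed, ...)
  if (n_boot > 0) fit <- pls_bootstrap(fit, n_boot = n_boot, seed = seed, ...)
  fit
}

refit_singular_values <- function(fit, X) {
  M <- if (fit$method == "behavioral")
    cross_correlation(X, fit$Y, fit$groups)
  else {
    G <- apply(X, 2, function(col) tapply(col, fit$groups, mean))
    sweep(G, 2, colMeans(G))
  }
  svd(M, nu = 0, nv = 0)$d
}

#' Permutation test for latent-variable significance
#'
#' Reshuffles the subject rows of the brain matrix (breaking their linkage
#' to the fixed group labels and behavior rows), refits, and records the
#' permuted singular values. The p-value per LV is the proportion of
#' permuted singular values at least as large as the observed one, with
#' the `(count + 1) / (n_perm + 1)` adjustment by default so p is never
#' exactly 0; `smoothing = FALSE` gives the raw proportion.
#'
#' @param fit a `bbpls` object.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; fixed seeds give bit-identical p-values.
#' @param smoothing use the add-one adjustment (default `TRUE`).
#' @param scheme `"across"` permutes rows over the whole sample (default);
#'   `"within"` permutes within group.
#' @return The fit with a `perm` element (`p`, `n_perm`, `sv` matrix of
#'   permuted singular values).
#' @export
pls_permutation <- function(fit, n_perm = 1000, seed = NULL, smoothing = TRUE,
                            scheme = c("across", "within")) {
  scheme <- match.arg(scheme)
  if (!inherits(fit, "bbpls")) stop("fit must be a bbpls object")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fit$X)
  k <- length(fit$singular_values)
  sv <- matrix(NA_real_, n_perm, k)
  for (p in seq_len(n_perm)) {
    ord <- if (scheme == "across") sample.int(n) else {
      o <- seq_len(n)
      for (g in levels(fit$groups)) {
        idx <- which(fit$groups == g)
        o[idx] <- sample(idx)
      }
      o
    }
    d <- refit_singular_values(fit, fit$X[ord, , drop = FALSE])
    sv[p, ] <- d[seq_len(k)]
  }
  counts <- colSums(sweep(sv, 2, fit$singular_values, `>=`))
  fit$perm <- list(
    p = if (smoothing) (counts + 1) / (n_perm + 1) else counts / n_perm,
    n_perm = n_perm, sv = sv)
  fit
}

# Orthogonal Procrustes rotation aligning columns of B to columns of A.
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))
  s$u %*% t(s$v)
}

#' Bootstrap reliability of PLS saliences
#'
#' Draws bootstrap samples by resampling subjects with replacement within
#' each group (stratified, preserving group sizes), refits the PLS, aligns
#' each bootstrap solution to the original (orthogonal Procrustes rotation
#' of the singular vectors by default, sign matching if
#' `procrustes = FALSE`), and accumulates the bootstrap distribution of the
#' saliences. The bootstrap ratio (BSR) of a brain variable is its original
#' salience divided by the bootstrap standard error; |BSR| >= 2
#' (approximately a 95% confidence criterion) flags a reliable
#' contribution. Percentile 95% CIs are reported for the behavior/design
#' saliences.
#'
#' A resample that leaves a brain or behavior column with zero variance in
#' some group is redrawn, with a capped retry count.
#'
#' @param fit a `bbpls` object.
#' @param n_boot bootstrap samples (default 500).
#' @param seed integer seed; fixed seeds give identical BSRs.
#' @param bsr_threshold reliability cutoff on |BSR| (default 2).
#' @param procrustes align bootstrap solutions by Procrustes rotation
#'   (default) or by per-LV sign matching.
#' @param max_redraw cap on redraws of degenerate resamples.
#' @return The fit with a `boot` element: `bsr`, `salience_se`,
#'   `reliable`, `u_ci_lower`/`u_ci_upper`, `n_boot`.
#' @export
pls_bootstrap <- function(fit, n_boot = 500, seed = NULL, bsr_threshold = 2,
                          procrustes = TRUE, max_redraw = 100L) {
  if (!inherits(fit, "bbpls")) stop("fit must be a bbpls object")
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (any(table(fit$groups) < 2L)) stop("every group needs >= 2 subjects")
  if (!is.null(seed)) set.seed(seed + 1L)  # decouple from permutation stream
  k <- length(fit$singular_values)
  p <- nrow(fit$brain_saliences)
  vboot <- array(NA_real_, c(p, k, n_boot))
  uboot <- array(NA_real_, c(nrow(fit$u), k, n_boot))
  g_idx <- split(seq_along(fit$groups), fit$groups)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(max_redraw)) {
      idx <- unlist(lapply(g_idx, function(ii) sample(ii, length(ii),
                                                      replace = TRUE)),
                    use.names = FALSE)
      Xb <- fit$X[idx, , drop = FALSE]
      ok <- all(apply(Xb, 2, stats::sd) > 0)
      if (ok && fit$method == "behavioral") {
        Yb <- fit$Y[idx, , drop = FALSE]
        for (g in levels(fit$groups)) {
          gi <- fit$groups[idx] == g
          ok <- ok && all(apply(Xb[gi, , drop = FALSE], 2, stats::sd) > 0) &&
            all(apply(Yb[gi, , drop = FALSE], 2, stats::sd) > 0)
        }
      }
      if (ok) break
      if (try == max_redraw) stop("could not draw a non-degenerate resample")
    }
    M <- if (fit$method == "behavioral")
      cross_correlation(Xb, fit$Y[idx, , drop = FALSE], fit$groups[idx])
    else {
      G <- apply(Xb, 2, function(col) tapply(col, fit$groups[idx], mean))
      sweep(G, 2, colMeans(G))
    }
    sb <- svd(M)
    Vb <- sb$v[, seq_len(k), drop = FALSE]
    Ub <- sb$u[, seq_len(k), drop = FALSE]
    if (procrustes) {
      Q <- procrustes_rotation(fit$brain_saliences, Vb)
      Vb <- Vb %*% Q
      Ub <- Ub %*% Q
    } else {
      for (j in seq_len(k)) {
        if (sum(Vb[, j] * fit$brain_saliences[, j]) < 0) {
          Vb[, j] <- -Vb[, j]
          Ub[, j] <- -Ub[, j]
        }
      }
    }
    vboot[, , b] <- Vb
    uboot[, , b] <- Ub
  }
  se <- apply(vboot, c(1, 2), stats::sd)
  bsr <- fit$brain_saliences / se
  bsr[se == 0] <- sign(fit$brain_saliences[se == 0]) * Inf
  dimnames(bsr) <- dimnames(fit$brain_saliences)
  u_lo <- apply(uboot, c(1, 2), stats::quantile, probs = 0.025)
  u_hi <- apply(uboot, c(1, 2), stats::quantile, probs = 0.975)
  fit$boot <- list(
    bsr = bsr,
    salience_se = structure(se, dimnames = dimnames(fit$brain_saliences)),
    reliable = abs(bsr) >= bsr_threshold,
    bsr_threshold = bsr_threshold,
    u_ci_lower = structure(u_lo, dimnames = dimnames(fit$u)),
    u_ci_upper = structure(u_hi, dimnames = dimnames(fit$u)),
    n_boot = n_boot)
  fit
}

#' @export
print.bbpls <- function(x, ...) {
  cat(sprintf("<bbpls> %s PLS: %d subjects, %d brain variables, %d LV(s)\n",
              x$method, nrow(x$X), ncol(x$X), length(x$singular_values)))
  tab <- data.frame(
    singular_value = round(x$singular_values, 4),
    cov_explained = round(x$cov_explained, 4))
  if (!is.null(x$perm)) tab$perm_p <- signif(x$perm$p, 3)
  rownames(tab) <- paste0("LV", seq_along(x$singular_values))
  print(tab)
  invisible(x)
}

#' @export
summary.bbpls <- function(object, lv = 1, ...) {
  print(object)
  if (!is.null(object$boot)) {
    nrel <- sum(object$boot$reliable[, lv])
    cat(sprintf(
      "\nLV%d: %d/%d brain variable(s) reliable at |BSR| >= %g (%d bootstraps)\n",
      lv, nrel, nrow(object$boot$bsr), object$boot$bsr_threshold,
      object$boot$n_boot))
    blk <- if (object$method == "behavioral") "behavior" else "design"
    ci <- cbind(salience = object$u[, lv],
                lo = object$boot$u_ci_lower[, lv],
                hi = object$boot$u_ci_upper[, lv])
    cat(sprintf("%s saliences (95%% bootstrap CI):\n", blk))
    print(round(ci, 3))
  }
  invisible(object)
}

#' @export
coef.bbpls <- function(object, lv = 1, ...) {
  object$brain_saliences[, lv]
}

#' Plot PLS bootstrap ratios or saliences
#'
#' Barplot of per-brain-variable bootstrap ratios for one latent variable,
#' with the reliability threshold marked, or (for `what = "behavior"`) the
#' behavior/design saliences with their bootstrap CIs.
#'
#' @param x a `bbpls` fit with bootstrap results.
#' @param lv latent variable to display.
#' @param what `"bsr"` or `"behavior"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bbpls <- function(x, lv = 1, what = c("bsr", "behavior"), ...) {
  what <- match.arg(what)
  if (is.null(x$boot)) stop("fit has no bootstrap results; rerun with n_boot > 0")
  if (what == "bsr") {
    graphics::barplot(x$boot$bsr[, lv], las = 2,
                      ylab = sprintf("bootstrap ratio (LV%d)", lv), ...)
    graphics::abline(h = c(-1, 1) * x$boot$bsr_threshold, lty = 2)
  } else {
    mid <- graphics::barplot(x$u[, lv], las = 2,
                             ylab = sprintf("salience (LV%d)", lv),
                             ylim = range(0, x$boot$u_ci_lower[, lv],
                                          x$boot$u_ci_upper[, lv]), ...)
    graphics::arrows(mid, x$boot$u_ci_lower[, lv],
                     mid, x$boot$u_ci_upper[, lv],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}
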