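# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# Sample entropy by explicit Chebyshev distance matrices built from shifted
# vectors (matrix algebra route, vs the package's compiled pair loop).
# Templates of length m and m+1 both start at 1..(n-m); pairs i < j.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  tol <- r * sd(x)
  nt <- n - m
  cheb <- function(len) {
    D <- matrix(0, nt, nt)
    for (k in seq_len(len) - 1L) {
      xk <- x[(1:nt) + k]
      D <- pmax(D, abs(outer(xk, xk, "-")))
    }
    D
  }
  B <- sum(cheb(m)[upper.tri(matrix(0, nt, nt))] <= tol)
  A <- sum(cheb(m + 1L)[upper.tri(matrix(0, nt, nt))] <= tol)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# All-pairs shortest paths by Floyd-Warshall over reciprocal-weight edge
# lengths; returns global efficiency.
ge_oracle <- function(w, symmetrize = TRUE) {
  if (symmetrize) w <- (w + t(w)) / 2
  R <- nrow(w)
  d <- matrix(Inf, R, R)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in 1:R) for (i in 1:R) for (j in 1:R)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (R * (R - 1))
}

# Random non-negative symmetric weight matrix on R nodes; edges present
# with probability dens.
random_weights <- function(R, dens = 0.5) {
  w <- matrix(0, R, R)
  ut <- upper.tri(w)
  present <- runif(sum(ut)) < dens
  vals <- ifelse(present, runif(sum(ut), 0.1, 2), 0)
  w[ut] <- vals
  w + t(w)
}

# Tiny synthetic study shared by several tests.
small_config <- function(seed = 11L, ...) {
  simulation_config(n_per_group = c(A = 6L, B = 6L), n_rois = 8L,
                    n_timepoints = 120L, n_csf_voxels = 10L,
                    seed = seed, ...)
}
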