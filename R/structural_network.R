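#' Zero structural weights absent from an anatomical-presence mask
#'
#' Structural connectivity matrices estimated by probabilistic tractography
#' contain false-positive edges; thresholding against a binary matrix of
#' anatomically documented connections (a CoCoMac-style presence mask)
#' removes them. Weights where the mask is `FALSE` are set to exactly 0,
#' all others pass through unchanged.
#'
#' @param weights R x R non-negative numeric matrix, zero diagonal.
#' @param mask R x R logical (or 0/1) matrix; `FALSE` marks connections to
#'   remove.
#' @return The masked weight matrix.
#' @export
apply_presence_mask <- function(weights, mask) {
  weights <- as.matrix(weights)
  mask <- as.matrix(mask)
  if (!all(dim(weights) == dim(mask)))
    stop("weights (", paste(dim(weights), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") dimensions differ")
  mode(mask) <- "logical"
  weights[!mask] <- 0
  weights
}

#' Weighted global efficiency of a structural network
#'
#' Global efficiency (GE) is the average inverse shortest-path length over
#' all ordered node pairs, a summary of a network's capacity for parallel
#' information transfer. Edge lengths are the reciprocals of the (positive)
#' weights; shortest paths are computed by Dijkstra's algorithm over those
#' lengths; disconnected pairs contribute 0 (the 1/Inf convention).
#' A complete graph with unit weights has GE exactly 1; an edgeless graph
#' has GE 0.
#'
#' Tractography output can be asymmetric. Because GE is used here as an
#' undirected summary, the matrix is symmetrized by the arithmetic mean of
#' the (i, j) and (j, i) entries before the computation; pass
#' `symmetrize = FALSE` to treat the weights as directed.
#'
#' @param weights R x R non-negative numeric matrix of connection weights,
#'   zero diagonal, R >= 2.
#' @param symmetrize average weights across the diagonal first (default).
#' @return Scalar GE >= 0.
#' @export
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0
#' global_efficiency(w)  # complete unit graph: 1
global_efficiency <- function(weights, symmetrize = TRUE) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  R <- nrow(w)
  if (R < 2L) stop("need at least 2 nodes")
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < 0)) stop("negative weights are not allowed")
  if (symmetrize) w <- (w + t(w)) / 2
  diag(w) <- 0
  lengths <- w
  lengths[w > 0] <- 1 / w[w > 0]
  lengths[w == 0] <- 0  # igraph: 0 means no edge below
  g <- igraph::graph_from_adjacency_matrix(
    lengths, mode = if (symmetrize) "undirected" else "directed",
    weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (R * (R - 1))
}

#' Regress a nuisance covariate out of per-subject scalars
#'
#' Ordinary least-squares residualization of a vector of per-subject values
#' (e.g. global efficiency) on an intercept plus one covariate (e.g. mean
#' framewise displacement), with the grand mean added back so the output
#' stays on the original scale. The residualized values have exactly zero
#' sample correlation with the covariate.
#'
#' @param values numeric vector, length >= 3.
#' @param covariate numeric vector of the same length; must not be constant.
#' @return Numeric vector of residualized values.
#' @export
residualize <- function(values, covariate) {
  values <- as.numeric(values)
  covariate <- as.numeric(covariate)
  if (length(values) != length(covariate))
    stop("values and covariate lengths differ")
  if (length(values) < 3L) stop("need at least 3 subjects")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  fit <- stats::lm(values ~ covariate)
  as.numeric(stats::residuals(fit)) + mean(values)
}
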