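#' Configuration for the synthetic study generator
#'
#' Collects the knobs of the synthetic-data generators in one validated
#' list. The defaults mirror the study conditions the package's analyses
#' assume: two groups of 20 and 17 subjects, 82 cortical ROIs, 180 TRs per
#' series, and behavior built from a planted low-rank brain-behavior
#' covariance (positive loadings for global efficiency, age and IQ,
#' negative for symptom severity).
#'
#' @param n_per_group named integer vector of subjects per group.
#' @param n_rois number of regions.
#' @param n_timepoints series length in TRs.
#' @param n_csf_voxels noise-reference voxels per subject.
#' @param ar_range range of the per-subject lag-1 AR coefficient; higher
#'   values give smoother series (lower MSSD and entropy). Must lie between
#'   0 and 0.95.
#' @param planted_salience unit-norm weight vector over ROIs defining the
#'   planted brain pattern; default: equal weights on the first
#'   `ceiling(0.23 * n_rois)` ROIs (about the fraction of reliable regions
#'   the method is expected to flag), zero elsewhere.
#' @param effect_size slope linking the latent brain score to each behavior
#'   column; 0 gives null (no brain-behavior linkage) data.
#' @param noise_sd SD of the additive noise on behavior columns.
#' @param behavior_signs named signs for the generated behavior columns.
#' @param sc_density fraction of anatomically present edges in the
#'   structural presence mask.
#' @param seed base random seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = c(ASD = 20L, TD = 17L),
                              n_rois = 82L,
                              n_timepoints = 180L,
                              n_csf_voxels = 30L,
                              ar_range = c(0.1, 0.6),
                              planted_salience = NULL,
                              effect_size = 3,
                              noise_sd = 0.5,
                              behavior_signs = c(ge = 1, age = 1,
                                                 iq = 1, srs = -1),
                              sc_density = 0.3,
                              seed = 1L) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("g", seq_along(n_per_group))
  stopifnot(all(n_per_group >= 1), n_rois >= 2, n_timepoints >= 3,
            n_csf_voxels >= 2, length(ar_range) == 2)
  if (ar_range[1] < 0 || ar_range[2] > 0.95 || ar_range[1] > ar_range[2])
    stop("ar_range must be within [0, 0.95] and ordered")
  if (is.null(planted_salience)) {
    k <- ceiling(0.23 * n_rois)
    planted_salience <- c(rep(1, k), rep(0, n_rois - k))
    planted_salience <- planted_salience / sqrt(sum(planted_salience^2))
  }
  if (length(planted_salience) != n_rois)
    stop("planted_salience length must equal n_rois")
  nrm <- sqrt(sum(planted_salience^2))
  if (abs(nrm - 1) > 1e-8)
    planted_salience <- planted_salience / nrm
  if (sc_density <= 0 || sc_density > 1)
    stop("sc_density must be in (0, 1]")
  structure(list(n_per_group = n_per_group, n_rois = n_rois,
                 n_timepoints = n_timepoints, n_csf_voxels = n_csf_voxels,
                 ar_range = ar_range, planted_salience = planted_salience,
                 effect_size = effect_size, noise_sd = noise_sd,
                 behavior_signs = behavior_signs, sc_density = sc_density,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_subject_ids <- function(config) {
  grp <- rep(names(config$n_per_group), config$n_per_group)
  data.frame(subject_id = sprintf("sub-%03d", seq_along(grp)),
             group = grp, stringsAsFactors = FALSE)
}

# Stationary AR(1) series of length n with coefficient phi and unit
# marginal variance.
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov_sd * stats::rnorm(1)
  x
}

#' Generate synthetic ROI BOLD time series
#'
#' One AR(1) series per subject and ROI, z-normalized. The lag-1
#' coefficient controls both MSSD (population value `2 * (1 - phi)` after
#' z-scoring) and sample entropy, so generated cohorts have a known
#' variability/complexity ordering.
#'
#' ROIs carrying nonzero planted-salience weight share a subject-level
#' coefficient (drawn uniformly from `ar_range`, lightly jittered per ROI),
#' emulating a *distributed* set of regions whose signal variability covaries
#' across subjects — the structure a brain-behavior analysis is meant to
#' find. Zero-weight ROIs draw independent coefficients, so they carry no
#' shared signal.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @return Named list of [roi_ts] objects, one per subject, with a
#'   `"phi"` attribute storing each subject's per-ROI AR coefficients.
#' @export
generate_bold <- function(config, seed = config$seed) {
  set.seed(seed)
  subj <- sim_subject_ids(config)
  labels <- sprintf("roi%03d", seq_len(config$n_rois))
  planted <- config$planted_salience != 0
  out <- vector("list", nrow(subj))
  names(out) <- subj$subject_id
  for (i in seq_len(nrow(subj))) {
    phi_s <- stats::runif(1, config$ar_range[1], config$ar_range[2])
    phis <- stats::runif(config$n_rois, config$ar_range[1],
                         config$ar_range[2])
    phis[planted] <- phi_s + stats::rnorm(sum(planted), 0, 0.03)
    phis <- pmin(pmax(phis, 0), 0.95)
    mat <- vapply(phis, function(p) ar1_series(config$n_timepoints, p),
                  numeric(config$n_timepoints))
    ts <- roi_ts(znormalize(mat), subj$subject_id[i], subj$group[i], labels)
    attr(ts, "phi") <- phis
    out[[i]] <- ts
  }
  out
}

#' Generate noise-reference (CSF) voxel sets
#'
#' Independent standard-normal series for every voxel: white noise is the
#' appropriate reference for entropy-parameter calibration because its
#' entropy is stable wherever estimation succeeds at all.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @return Named list of V x T matrices, one per subject.
#' @export
generate_csf <- function(config, seed = config$seed) {
  set.seed(seed + 1000L)
  subj <- sim_subject_ids(config)
  out <- lapply(seq_len(nrow(subj)), function(i)
    matrix(stats::rnorm(config$n_csf_voxels * config$n_timepoints),
           nrow = config$n_csf_voxels))
  names(out) <- subj$subject_id
  out
}

#' Generate structural connectivity matrices and a presence mask
#'
#' Draws one symmetric binary presence mask at density `sc_density`
#' (shared by all subjects, mimicking an anatomical-connection database)
#' and, per subject, non-negative symmetric weights on the present edges.
#' A per-subject multiplicative "efficiency knob" scales the weights so
#' global efficiency varies across subjects in a known ordering (on fully
#' connected graphs GE scales exactly linearly with the knob).
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @return List with elements `weights` (named list of R x R matrices),
#'   `mask` (logical R x R), and `knob` (named numeric vector).
#' @export
generate_sc <- function(config, seed = config$seed) {
  set.seed(seed + 2000L)
  subj <- sim_subject_ids(config)
  R <- config$n_rois
  mask <- matrix(FALSE, R, R)
  ut <- upper.tri(mask)
  n_edges <- max(1L, round(config$sc_density * sum(ut)))
  mask[sample(which(ut), n_edges)] <- TRUE
  mask <- mask | t(mask)
  knob <- stats::runif(nrow(subj), 0.5, 1.5)
  names(knob) <- subj$subject_id
  weights <- lapply(seq_len(nrow(subj)), function(i) {
    w <- matrix(0, R, R)
    w[ut] <- stats::runif(sum(ut), 0.5, 1.5)
    w <- (w + t(w)) * knob[i]
    w[!mask] <- 0
    diag(w) <- 0
    w
  })
  names(weights) <- subj$subject_id
  list(weights = weights, mask = mask, knob = knob)
}

#' Generate behavior variables with a planted brain-behavior covariance
#'
#' Projects each subject's brain metric row onto the planted salience to
#' obtain a latent score `s`, then builds each behavior column as
#' `effect_size * sign * s + noise`, z-normalized. With `effect_size = 0`
#' the behavior block is pure noise (the null condition). A head-motion
#' (`fd`) column uncorrelated with the latent score is always appended as
#' a nuisance covariate.
#'
#' @param brain_matrix subjects x ROI metric matrix (e.g. from
#'   [metric_matrix()]).
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @return Data.frame with `subject_id`, `group`, one z-scored column per
#'   entry of `config$behavior_signs`, and `fd`; the latent score is kept
#'   in the `"latent"` attribute.
#' @export
generate_behavior <- function(brain_matrix, config, seed = config$seed) {
  set.seed(seed + 3000L)
  if (ncol(brain_matrix) != length(config$planted_salience))
    stop("brain_matrix columns (", ncol(brain_matrix),
         ") do not match planted_salience length (",
         length(config$planted_salience), ")")
  subj <- sim_subject_ids(config)
  if (nrow(brain_matrix) != nrow(subj))
    stop("brain_matrix rows do not match configured subject count")
  s <- as.numeric(scale(brain_matrix %*% config$planted_salience))
  cols <- lapply(names(config$behavior_signs), function(nm) {
    raw <- config$effect_size * config$behavior_signs[[nm]] * s +
      stats::rnorm(length(s), 0, config$noise_sd)
    as.numeric(scale(raw))
  })
  names(cols) <- names(config$behavior_signs)
  out <- cbind(subj, as.data.frame(cols),
               fd = as.numeric(scale(stats::rnorm(length(s)))))
  attr(out, "latent") <- s
  out
}

#' Simulate a complete synthetic study
#'
#' Runs all four generators with one base seed and returns the full input
#' bundle the pipeline consumes: BOLD series, CSF voxel sets, structural
#' matrices with presence mask, and a behavior table whose `ge` column is
#' replaced by each subject's actual masked global efficiency (so the
#' table mixes planted structure with a genuinely computed graph metric).
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @param behavior_metric metric used to build the planted behavior block.
#' @return List with `bold`, `csf`, `sc`, `behavior`, `config`.
#' @export
simulate_study <- function(config = simulation_config(),
                           seed = config$seed,
                           behavior_metric = "mssd") {
  bold <- generate_bold(config, seed)
  csf <- generate_csf(config, seed)
  sc <- generate_sc(config, seed)
  bm <- suppressWarnings(metric_matrix(bold, behavior_metric))
  behavior <- generate_behavior(bm, config, seed)
  ge <- vapply(sc$weights, function(w)
    global_efficiency(apply_presence_mask(w, sc$mask)), numeric(1))
  behavior$ge_raw <- ge[behavior$subject_id]
  list(bold = bold, csf = csf, sc = sc, behavior = behavior, config = config)
}
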