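#' Read / write tab-separated numeric matrices
#'
#' Plain-text interchange used throughout the pipeline: TSV with a header
#' row, no row names. `read_matrix_tsv` returns a numeric matrix.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(x)))
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param header does the file carry a header row (default `TRUE`).
#' @export
read_matrix_tsv <- function(path, header = TRUE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = header,
                                   check.names = FALSE))
  if (!header) dimnames(m) <- NULL
  m
}

#' Write a simulated study to a directory of plain-text files
#'
#' Materializes the bundle from [simulate_study()] in the on-disk layout
#' the pipeline reads: a manifest (`subject_id`, `group`, relative paths),
#' per-subject time-series and CSF TSVs, per-subject structural weight
#' matrices, the shared presence mask, and the behavior table as CSV.
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  for (d in file.path(dir, c("series", "csf", "sc")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ids <- names(study$bold)
  for (id in ids) {
    write_matrix_tsv(unclass(study$bold[[id]]),
                     file.path(dir, "series", paste0(id, ".tsv")))
    write_matrix_tsv(study$csf[[id]],
                     file.path(dir, "csf", paste0(id, ".tsv")))
    write_matrix_tsv(study$sc$weights[[id]],
                     file.path(dir, "sc", paste0(id, ".tsv")))
  }
  write_matrix_tsv(study$sc$mask * 1L, file.path(dir, "mask.tsv"))
  manifest <- data.frame(
    subject_id = ids,
    group = vapply(study$bold, attr, "", "group"),
    series = file.path("series", paste0(ids, ".tsv")),
    csf = file.path("csf", paste0(ids, ".tsv")),
    sc = file.path("sc", paste0(ids, ".tsv")))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(study$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a study directory back into memory
#'
#' @param dir directory produced by [write_study()] (or hand-assembled in
#'   the same layout).
#' @return List with `bold`, `csf`, `sc` (`weights` + `mask`), `behavior`,
#'   `manifest`.
#' @export
read_study <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  bold <- lapply(seq_len(nrow(manifest)), function(i)
    roi_ts(read_matrix_tsv(file.path(dir, manifest$series[i])),
           manifest$subject_id[i], manifest$group[i]))
  names(bold) <- manifest$subject_id
  csf <- lapply(manifest$csf, function(p)
    read_matrix_tsv(file.path(dir, p), header = FALSE))
  names(csf) <- manifest$subject_id
  weights <- lapply(manifest$sc, function(p)
    read_matrix_tsv(file.path(dir, p), header = FALSE))
  names(weights) <- manifest$subject_id
  mask <- read_matrix_tsv(file.path(dir, "mask.tsv"), header = FALSE) > 0
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
                              stringsAsFactors = FALSE)
  if (!all(behavior$subject_id == manifest$subject_id))
    stop("subject sets differ between manifest and behavior table: ",
         paste(setdiff(manifest$subject_id, behavior$subject_id),
               collapse = ", "))
  list(bold = bold, csf = csf, sc = list(weights = weights, mask = mask),
       behavior = behavior, manifest = manifest)
}

#' End-to-end analysis pipeline
#'
#' Runs the full analysis on a study directory: signal metrics (MSSD),
#' entropy-parameter calibration on the CSF sets, condition-averaged
#' sample entropy, masked global efficiency with head-motion
#' residualization, mean-centering PLS for the group contrast, behavioral
#' PLS against (GE, age, IQ, severity), and the univariate group
#' statistics. All tabular outputs are written to `out_dir` as TSV, the
#' result summary as JSON, and a provenance log (seed, versions, config
#' hash) alongside. Rerunning with identical inputs and seed reproduces
#' every output byte-for-byte.
#'
#' @param input_dir study directory in the [write_study()] layout.
#' @param out_dir output directory (created if needed).
#' @param m_values,r_values,se_threshold calibration grid specification.
#' @param average_m,exclude_r condition-averaging rule: average the
#'   acceptable conditions at this pattern length, dropping the listed
#'   tolerances (defaults: m = 2, drop r = 0.20).
#' @param behavior_vars behavior columns used in the behavioral PLS; the
#'   `"ge"` entry is computed from the structural matrices, residualized on
#'   `fd_var`, and injected.
#' @param fd_var head-motion column name in the behavior table.
#' @param n_perm,n_boot,seed,bsr_threshold PLS inference settings.
#' @return List of class `boldvar_run` with `mssd`, `entropy`, `grid`,
#'   `efficiency`, `pls_group_mssd`, `pls_group_entropy`, `pls_behavior`,
#'   `stats`, `provenance`, invisibly written to `out_dir`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         m_values = 1:4,
                         r_values = seq(0.05, 0.80, by = 0.05),
                         se_threshold = 0.1,
                         average_m = 2L,
                         exclude_r = 0.20,
                         behavior_vars = c("ge", "age", "iq", "srs"),
                         fd_var = "fd",
                         n_perm = 1000, n_boot = 500, seed = 1L,
                         bsr_threshold = 2) {
  study <- read_study(input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- factor(study$manifest$group)

  ## 1. variability
  mssd_mat <- metric_matrix(study$bold, "mssd")
  write_matrix_tsv(mssd_mat, file.path(out_dir, "mssd.tsv"))

  ## 2. entropy calibration + condition averaging
  grid <- calibrate_entropy_grid(study$csf, m_values, r_values, se_threshold)
  utils::write.table(as.data.frame(grid), file.path(out_dir, "calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conds <- acceptable_conditions(grid, m = average_m, exclude_r = exclude_r)
  if (nrow(conds) == 0L)
    stop("no acceptable entropy conditions at m = ", average_m,
         "; inspect the calibration grid")
  ent_arr <- entropy_condition_array(study$bold, conds)
  entropy_mat <- suppressWarnings(
    average_over_conditions(ent_arr, conds, grid))
  write_matrix_tsv(entropy_mat, file.path(out_dir, "entropy.tsv"))

  ## 3. structural efficiency, motion-residualized
  ge <- vapply(study$sc$weights, function(w)
    global_efficiency(apply_presence_mask(w, study$sc$mask)), numeric(1))
  fd <- study$behavior[[fd_var]]
  ge_resid <- residualize(ge, fd)
  eff <- data.frame(subject_id = study$manifest$subject_id,
                    ge = ge, ge_residualized = ge_resid)
  utils::write.table(eff, file.path(out_dir, "efficiency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## 4. PLS
  if (anyNA(entropy_mat))
    stop("entropy matrix contains estimation failures; ",
         "choose different conditions")
  behavior <- study$behavior
  behavior$ge <- ge_resid
  Y <- as.matrix(behavior[, behavior_vars, drop = FALSE])
  pls_group_mssd <- mean_centering_pls(mssd_mat, groups,
                                       n_perm = n_perm, n_boot = n_boot,
                                       seed = seed)
  pls_group_entropy <- mean_centering_pls(entropy_mat, groups,
                                          n_perm = n_perm, n_boot = n_boot,
                                          seed = seed)
  pls_behavior <- behavioral_pls(mssd_mat, Y, groups,
                                 n_perm = n_perm, n_boot = n_boot,
                                 seed = seed)
  for (nm in c("pls_group_mssd", "pls_group_entropy", "pls_behavior")) {
    fit <- get(nm)
    write_matrix_tsv(fit$brain_saliences,
                     file.path(out_dir, paste0(nm, "_brain_saliences.tsv")))
    write_matrix_tsv(fit$boot$bsr,
                     file.path(out_dir, paste0(nm, "_bsr.tsv")))
  }

  ## 5. univariate statistics
  split_vals <- function(v) split(v, groups)
  gstats <- lapply(behavior_vars, function(nm) {
    v <- split_vals(behavior[[nm]])
    res <- pooled_t(v[[1]], v[[2]])
    data.frame(variable = nm, t = res$statistic, df = res$df, p = res$p)
  })
  stats_tab <- do.call(rbind, gstats)
  utils::write.table(stats_tab, file.path(out_dir, "group_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 6. summary JSON + provenance
  summary <- list(
    n_subjects = nrow(study$manifest),
    groups = as.list(table(groups)),
    acceptable_conditions = nrow(acceptable_conditions(grid)),
    averaged_conditions = nrow(conds),
    pls = list(
      group_mssd_p = pls_group_mssd$perm$p[1],
      group_entropy_p = pls_group_entropy$perm$p[1],
      behavior_p = pls_behavior$perm$p[1],
      behavior_cov_explained = pls_behavior$cov_explained[1],
      behavior_n_reliable = sum(pls_behavior$boot$reliable[, 1])))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(m_values = m_values, r_values = r_values,
              se_threshold = se_threshold, average_m = average_m,
              exclude_r = exclude_r, behavior_vars = behavior_vars,
              n_perm = n_perm, n_boot = n_boot, seed = seed,
              bsr_threshold = bsr_threshold)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- c(
    sprintf("package: boldvar %s",
            as.character(utils::packageVersion("boldvar"))),
    sprintf("R: %s", R.version.string),
    sprintf("seed: %d", seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))))
  writeLines(prov, file.path(out_dir, "provenance.txt"))

  res <- list(mssd = mssd_mat, entropy = entropy_mat, grid = grid,
              efficiency = eff, pls_group_mssd = pls_group_mssd,
              pls_group_entropy = pls_group_entropy,
              pls_behavior = pls_behavior, stats = stats_tab,
              provenance = prov)
  class(res) <- "boldvar_run"
  invisible(res)
}

#' @export
print.boldvar_run <- function(x, ...) {
  cat("<boldvar_run>\n")
  cat(sprintf("  subjects: %d, ROIs: %d\n", nrow(x$mssd), ncol(x$mssd)))
  cat(sprintf("  acceptable conditions averaged: %d\n",
              attr(x$entropy, "n_conditions") %||% NA_integer_))
  cat(sprintf("  group PLS p (MSSD): %.3g, (entropy): %.3g\n",
              x$pls_group_mssd$perm$p[1], x$pls_group_entropy$perm$p[1]))
  cat(sprintf("  behavioral PLS p: %.3g (%.1f%% covariance explained)\n",
              x$pls_behavior$perm$p[1],
              100 * x$pls_behavior$cov_explained[1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
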