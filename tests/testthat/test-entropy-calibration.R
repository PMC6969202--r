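test_that("entropy SE is zero for identical voxels and matches the formula", {
  set.seed(3)
  v <- rnorm(150)
  same <- rbind(v, v, v)
  res <- entropy_se(same, 2, 0.5)
  expect_equal(res$se, 0)
  expect_equal(res$n_failures, 0)
  # formula check: SE = 1.96 * (sd/mean)^2 over per-voxel entropies
  vox <- matrix(rnorm(4 * 150), 4)
  ent <- apply(vox, 1, sample_entropy, m = 2, r = 0.5)
  res2 <- entropy_se(vox, 2, 0.5)
  expect_equal(res2$se, 1.96 * (sd(ent) / mean(ent))^2, tolerance = 1e-12)
  res3 <- entropy_se(vox, 2, 0.5, squared = FALSE)
  expect_equal(res3$se, 1.96 * (sd(ent) / mean(ent)), tolerance = 1e-12)
})

test_that("hand example: entropies {1,1,2,2} give SE = 1.96*(sd/1.5)^2", {
  # arithmetic frozen from the definition: mean 1.5, sd = sqrt(1/3)
  expect_equal(1.96 * (sqrt(1 / 3) / 1.5)^2, 0.2904, tolerance = 1e-3)
})

test_that("all-failed and degenerate voxel sets yield undefined SE", {
  ramps <- rbind(1:60, 2 * (1:60), 3 * (1:60))
  res <- entropy_se(ramps, 2, 0.05)
  expect_true(is.na(res$se))
  expect_equal(res$n_failures, 3)
  # constant voxels: entropy 0 everywhere -> mean 0 -> SE undefined
  const <- matrix(rep(1:2, each = 30), nrow = 2, ncol = 60, byrow = TRUE) * 0 + 1
  res2 <- entropy_se(rbind(rep(1, 60), rep(1, 60)), 1, 0.5)
  expect_true(is.na(res2$se))
})

test_that("white-noise reference voxels give stable entropy (SE < 0.1)", {
  set.seed(21)
  for (i in 1:20) {
    vox <- matrix(rnorm(15 * 180), 15)
    expect_lt(entropy_se(vox, 2, 0.5)$se, 0.1)
  }
})

test_that("calibration grid applies the acceptability rule exactly", {
  set.seed(8)
  csf <- replicate(3, matrix(rnorm(8 * 150), 8), simplify = FALSE)
  names(csf) <- paste0("s", 1:3)
  grid <- calibrate_entropy_grid(csf, m_values = 1:3,
                                 r_values = c(0.05, 0.2, 0.5))
  expect_equal(nrow(grid), 9)  # full Cartesian product
  # acceptable iff median_se < threshold AND zero failures
  expect_equal(grid$acceptable,
               !is.na(grid$median_se) & grid$median_se < 0.1 &
                 grid$n_failures == 0)
  # per-subject SEs recomputed independently match the stored matrix
  se_mat <- attr(grid, "per_subject_se")
  cell <- which(grid$m == 2 & grid$r == 0.5)
  redo <- sapply(csf, function(v) entropy_se(v, 2, 0.5)$se)
  expect_equal(unname(se_mat[cell, ]), unname(redo), tolerance = 1e-12)
  expect_equal(grid$median_se[cell], median(redo), tolerance = 1e-12)
})

test_that("any estimation failure disqualifies a cell regardless of SE", {
  set.seed(12)
  good <- matrix(rnorm(6 * 120), 6)
  with_ramp <- rbind(good[1:5, ], 1:120)  # one unmatchable voxel at small r
  csf <- list(s1 = with_ramp)
  grid <- calibrate_entropy_grid(csf, m_values = 2, r_values = 0.05)
  expect_gte(grid$n_failures[1], 1)
  expect_false(grid$acceptable[1])
})

test_that("failure counts are monotone in m and acceptability in threshold", {
  set.seed(31)
  csf <- replicate(2, matrix(rnorm(10 * 120), 10), simplify = FALSE)
  names(csf) <- c("a", "b")
  grid <- calibrate_entropy_grid(csf, m_values = 1:4,
                                 r_values = c(0.05, 0.1, 0.2))
  for (r in unique(grid$r)) {
    f <- grid$n_failures[grid$r == r][order(grid$m[grid$r == r])]
    expect_true(all(diff(f) >= 0))
  }
  loose <- calibrate_entropy_grid(csf, m_values = 1:4,
                                  r_values = c(0.05, 0.1, 0.2),
                                  se_threshold = 0.5)
  expect_true(all(!grid$acceptable | loose$acceptable))
})

test_that("constant reference voxels mark cells unacceptable, not an error", {
  csf <- list(s1 = matrix(1, 4, 60))
  grid <- calibrate_entropy_grid(csf, m_values = 2, r_values = 0.2)
  expect_false(grid$acceptable[1])
})

test_that("condition averaging is the cell-wise mean with NA exclusion", {
  arr <- array(NA_real_, c(2, 2, 3),
               dimnames = list(c("s1", "s2"), c("r1", "r2"),
                               c("m2_r0.25", "m2_r0.30", "m2_r0.35")))
  arr[, , 1] <- 1
  arr[, , 2] <- 2
  arr[, , 3] <- 3
  sel2 <- data.frame(m = 2, r = c(0.25, 0.30))
  expect_equal(unname(average_over_conditions(arr, sel2)),
               matrix(1.5, 2, 2), ignore_attr = TRUE)
  # single condition is the identity
  sel1 <- data.frame(m = 2, r = 0.25)
  expect_equal(unname(average_over_conditions(arr, sel1)), matrix(1, 2, 2),
               ignore_attr = TRUE)
  # failed cell excluded pairwise
  arr[1, 1, 1] <- NA
  expect_warning(avg <- average_over_conditions(arr, sel2), "excluded")
  expect_equal(avg[1, 1], 2)
  expect_equal(avg[2, 2], 1.5)
  expect_error(average_over_conditions(arr, sel2[0, ]), "empty")
})

test_that("averaging refuses unacceptable conditions unless overridden", {
  set.seed(8)
  csf <- list(s1 = matrix(rnorm(8 * 150), 8))
  grid <- calibrate_entropy_grid(csf, m_values = 2, r_values = c(0.2, 0.5))
  arr <- array(1, c(1, 2, 1), dimnames = list("s1", c("a", "b"), "m4_r0.05"))
  sel <- data.frame(m = 4, r = 0.05)
  expect_error(average_over_conditions(arr, sel, grid), "not flagged")
  expect_silent(average_over_conditions(arr, sel, grid,
                                        allow_unacceptable = TRUE))
})

test_that("the shipped default averages m = 2 with r = 0.20 excluded", {
  d <- default_entropy_conditions()
  expect_true(all(d$m == 2))
  expect_equal(d$r, seq(0.25, 0.65, by = 0.05))
  # acceptable_conditions applies an exclusion list
  g <- data.frame(m = 2, r = c(0.20, 0.25), median_se = 0.01,
                  n_failures = 0L, acceptable = TRUE)
  class(g) <- c("entropy_grid", "data.frame")
  sel <- acceptable_conditions(g, m = 2, exclude_r = 0.20)
  expect_equal(sel$r, 0.25)
})
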