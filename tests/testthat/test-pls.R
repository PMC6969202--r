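test_that("mean-centering PLS recovers closed-form group contrasts", {
  # identical group means: no contrast, all singular values 0
  X0 <- rbind(matrix(c(1, 2), 4, 2, byrow = TRUE),
              matrix(c(1, 2), 4, 2, byrow = TRUE))
  g <- rep(c("a", "b"), each = 4)
  fit0 <- mean_centering_pls(X0, g, n_perm = 0, n_boot = 0)
  expect_equal(fit0$singular_values, rep(0, 2), tolerance = 1e-12)

  # one brain variable, means a and b: singular value |a-b|/sqrt(2)
  set.seed(20)
  a <- 1.3; b <- -0.7
  X1 <- matrix(c(rnorm(5, a, 1e-8), rnorm(5, b, 1e-8)), ncol = 1)
  fit1 <- mean_centering_pls(X1, g <- rep(c("a", "b"), each = 5),
                             n_perm = 0, n_boot = 0)
  expect_equal(fit1$singular_values[1], abs(a - b) / sqrt(2),
               tolerance = 1e-6)

  # three conditions with means on a line: LV1 carries ~100% covariance
  mu <- rbind(c(0, 0), c(1, 2), c(2, 4))
  X2 <- mu[rep(1:3, each = 6), ] + matrix(rnorm(36, 0, 1e-6), 18, 2)
  fit2 <- mean_centering_pls(X2, rep(1:3, each = 6), n_perm = 0, n_boot = 0)
  expect_gt(fit2$cov_explained[1], 0.999999)
})

test_that("behavioral PLS on rank-1 data concentrates on the right column", {
  set.seed(21)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("roi", 1:5)))
  Y <- X[, 3, drop = FALSE]  # behavior IS brain column 3
  fit <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
  expect_equal(fit$cov_explained[1], 1, tolerance = 1e-10)
  expect_equal(which.max(abs(fit$brain_saliences[, 1])), 3L,
               ignore_attr = TRUE)
})

test_that("hand-computable 1-behavior SVD: singular value is the corr norm", {
  X <- matrix(c(1, 2, 4, 3,
                2, 1, 3, 5), 4, 2)
  Y <- matrix(c(1.5, 2, 3, 4), 4, 1)
  rvec <- c(cor(Y, X[, 1]), cor(Y, X[, 2]))
  fit <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
  expect_equal(fit$singular_values[1], sqrt(sum(rvec^2)), tolerance = 1e-12)
  expect_equal(abs(fit$brain_saliences[, 1]),
               abs(rvec) / sqrt(sum(rvec^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("single-group 1-behavior PLS reduces to the normalized corr vector", {
  set.seed(22)
  X <- matrix(rnorm(30 * 7), 30, 7)
  Y <- matrix(rnorm(30), 30, 1)
  fit <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
  rvec <- as.numeric(cor(Y, X))
  v <- rvec / sqrt(sum(rvec^2))
  i <- which.max(abs(fit$brain_saliences[, 1]))
  if (v[i] < 0) v <- -v  # package sign convention
  expect_equal(unname(fit$brain_saliences[, 1]), v, tolerance = 1e-12)
})

test_that("SVD invariants: energy conservation, orthonormality, scores", {
  set.seed(23)
  X <- matrix(rnorm(24 * 6), 24, 6)
  Y <- matrix(rnorm(24 * 3), 24, 3)
  g <- rep(c("a", "b"), each = 12)
  fit <- behavioral_pls(X, Y, g, n_perm = 0, n_boot = 0)
  expect_equal(sum(fit$singular_values^2), sum(fit$cross^2),
               tolerance = 1e-10)
  expect_equal(sum(fit$cov_explained), 1, tolerance = 1e-12)
  k <- length(fit$singular_values)
  expect_equal(crossprod(fit$brain_saliences), diag(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$behavior_saliences), diag(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(unname(fit$brain_scores),
                   unname(X %*% fit$brain_saliences))
})

test_that("refitting without resampling is bit-identical (sign convention)", {
  set.seed(24)
  X <- matrix(rnorm(20 * 4), 20, 4)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  f1 <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
  f2 <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
  expect_identical(f1$brain_saliences, f2$brain_saliences)
  expect_identical(f1$singular_values, f2$singular_values)
})

test_that("zero-variance columns are refused by name", {
  X <- cbind(roiA = rnorm(10), roiB = rep(1, 10))
  Y <- matrix(rnorm(10), 10, 1)
  expect_error(behavioral_pls(X, Y, n_perm = 0, n_boot = 0), "roiB")
  X2 <- matrix(rnorm(20), 10, 2)
  Y2 <- cbind(age = rep(3, 10))
  expect_error(behavioral_pls(X2, Y2, n_perm = 0, n_boot = 0), "age")
})

test_that("permutation p is deterministic under a fixed seed and floors on collinear data", {
  set.seed(25)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- matrix(X %*% rnorm(5), 30, 1)  # perfectly determined by X
  f1 <- behavioral_pls(X, Y, n_perm = 100, n_boot = 0, seed = 99)
  f2 <- behavioral_pls(X, Y, n_perm = 100, n_boot = 0, seed = 99)
  expect_identical(f1$perm$p, f2$perm$p)
  expect_equal(f1$perm$p[1], 1 / 101)  # minimum attainable with smoothing
  f3 <- pls_permutation(behavioral_pls(X, Y, n_perm = 0, n_boot = 0),
                        n_perm = 100, seed = 99, smoothing = FALSE)
  expect_equal(f3$perm$p[1], 0)
})

test_that("bootstrap is deterministic and BSRs explode on noiseless data", {
  set.seed(26)
  n <- 24
  s <- rnorm(n)
  X <- outer(s, c(1, 2, 0, 0)) + matrix(rnorm(4 * n, 0, 1e-4), n, 4)
  Y <- matrix(s, n, 1)
  f1 <- behavioral_pls(X, Y, n_perm = 0, n_boot = 100, seed = 5)
  f2 <- behavioral_pls(X, Y, n_perm = 0, n_boot = 100, seed = 5)
  expect_identical(f1$boot$bsr, f2$boot$bsr)
  expect_gt(abs(f1$boot$bsr[1, 1]), 20)
  expect_gt(abs(f1$boot$bsr[2, 1]), 20)
  expect_true(all(f1$boot$reliable[1:2, 1]))
})

test_that("bootstrap flags planted ROIs with good sensitivity at strong effect", {
  set.seed(27)
  cfg <- simulation_config(n_per_group = c(all = 40L), n_rois = 30L,
                           n_timepoints = 120L, effect_size = 3,
                           noise_sd = 0.3, seed = 27L)
  bold <- generate_bold(cfg)
  X <- metric_matrix(bold, "mssd")
  Y <- suppressWarnings(generate_behavior(X, cfg))
  fit <- suppressWarnings(
    behavioral_pls(X, as.matrix(Y[, c("ge", "age", "iq", "srs")]),
                   n_perm = 0, n_boot = 200, seed = 27))
  planted <- which(cfg$planted_salience != 0)
  sens <- mean(fit$boot$reliable[planted, 1])
  expect_gte(sens, 0.8)
})

test_that("mean-centering PLS permutation and bootstrap run and are stable", {
  set.seed(28)
  X <- rbind(matrix(rnorm(8 * 5, 0), 8, 5), matrix(rnorm(8 * 5, 2), 8, 5))
  g <- rep(c("a", "b"), each = 8)
  fit <- mean_centering_pls(X, g, n_perm = 200, n_boot = 100, seed = 3)
  expect_lt(fit$perm$p[1], 0.05)  # planted strong group shift
  expect_equal(dim(fit$boot$bsr), c(5L, 2L))
  expect_identical(
    fit$perm$p,
    mean_centering_pls(X, g, n_perm = 200, n_boot = 0, seed = 3)$perm$p)
})
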