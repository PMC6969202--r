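test_that("z-normalization gives mean 0, sd 1, and is idempotent", {
  m <- matrix(c(1, 2, 3, 2, 4, 6, 1, 1, 2), ncol = 3)
  z <- znormalize(m)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(unclass(znormalize(z)), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # hand-computed example, sample-sd convention
  z4 <- znormalize(matrix(c(2, 4, 6, 8), ncol = 1))
  expect_equal(as.numeric(z4), c(-1.1619, -0.3873, 0.3873, 1.1619),
               tolerance = 1e-4)
})

test_that("z-normalization refuses constant columns by name", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("ok", "flat")))
  expect_error(znormalize(m), "flat")
})

test_that("mssd matches hand arithmetic and degenerate cases", {
  expect_equal(mssd(rep(3.7, 10)), 0)
  for (n in c(3, 5, 8))
    expect_equal(mssd(rep_len(c(1, -1), n)), 4)
  expect_equal(mssd(c(0, 1, 3, 2, 5)), 15 / 4)
  expect_error(mssd(c(1, 2)), "at least 3")
})

test_that("mssd and sd are shift-invariant; entropy is affine-invariant", {
  set.seed(5)
  x <- rnorm(120)
  expect_equal(mssd(x + 100), mssd(x), tolerance = 1e-9)
  expect_equal(sd_metric(x + 100), sd_metric(x), tolerance = 1e-9)
  # tolerance scales with SD, so affine maps leave entropy unchanged
  expect_equal(sample_entropy(3.2 * x - 7, 2, 0.4),
               sample_entropy(x, 2, 0.4), tolerance = 1e-10)
  expect_equal(sample_entropy(-2 * x, 2, 0.4),
               sample_entropy(x, 2, 0.4), tolerance = 1e-10)
})

test_that("sd_metric uses the n-1 divisor", {
  expect_equal(sd_metric(c(0, 1, 3, 2, 5)), sqrt(14.8 / 4), tolerance = 1e-12)
  expect_equal(sd_metric(rep(2, 5)), 0)
  set.seed(2)
  expect_equal(sd_metric(as.numeric(znormalize(matrix(rnorm(50))))), 1,
               tolerance = 1e-12)
})

test_that("sample entropy handles constant, monotone, and random series", {
  expect_equal(sample_entropy(rep(1, 50), 2, 0.2), 0)
  expect_true(is.na(sample_entropy(as.numeric(1:10), 2, 0.05)))
  set.seed(42)
  x <- rnorm(180)
  expect_equal(sample_entropy(x, 2, 0.5), sampen_oracle(x, 2, 0.5),
               tolerance = 1e-12)
})

test_that("sample entropy input validation", {
  expect_error(sample_entropy(rnorm(4), 3, 0.2), "too short")
  expect_error(sample_entropy(rnorm(50), 2, -0.1), "positive tolerance")
  expect_error(sample_entropy(rnorm(50), 0, 0.2), "positive integer")
})

test_that("sample entropy equals the brute-force oracle over a seeded battery", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    x <- cumsum(rnorm(n)) + rnorm(n)  # mix of smooth and rough
    m <- sample(1:3, 1)
    r <- sample(c(0.2, 0.5), 1)
    got <- sample_entropy(x, m, r)
    want <- sampen_oracle(x, m, r)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("sample entropy is a valid negative log conditional probability", {
  # A <= B deterministically (an (m+1)-match implies an m-match), so
  # whenever the estimate is defined it is non-negative and exp(-SampEn)
  # is a probability in (0, 1]
  set.seed(9)
  for (i in 1:20) {
    x <- as.numeric(arima.sim(list(ar = runif(1, 0, 0.9)), 150))
    for (m in 1:3) for (r in c(0.2, 0.5)) {
      v <- sample_entropy(x, m, r)
      if (!is.na(v)) {
        expect_gte(v, 0)
        expect_lte(exp(-v), 1)
      }
    }
  }
})

test_that("metric_matrix is consistent with per-ROI calls and checks labels", {
  cfg <- small_config()
  bold <- generate_bold(cfg)
  mm <- metric_matrix(bold, "mssd")
  expect_equal(dim(mm), c(12, 8))
  s1 <- znormalize(bold[[3]])
  expect_equal(mm[3, ], apply(unclass(s1), 2, mssd), tolerance = 1e-12)
  em <- metric_matrix(bold, "sampen", m = 2, r = 0.5)
  expect_equal(em[5, 2],
               sample_entropy(unclass(znormalize(bold[[5]]))[, 2], 2, 0.5),
               tolerance = 1e-12)
  # constant series: all-zero MSSD
  flat <- list(roi_ts(matrix(rep(c(1, 2), each = 10), 10, 2), "s1", "A"))
  expect_equal(unname(metric_matrix(flat, "mssd", normalize = FALSE)),
               matrix(0, 1, 2))
  # label mismatch errors
  bad <- bold
  colnames(bad[[2]]) <- rev(colnames(bad[[2]]))
  expect_error(metric_matrix(bad, "mssd"), "ROI labels differ")
})

test_that("entropy failures propagate as NA cells with a warning", {
  ramp <- matrix(c(1:20, (1:20)^1.5), 20, 2)
  ds <- list(roi_ts(ramp, "s1", "A"))
  expect_warning(mm <- metric_matrix(ds, "sampen", m = 2, r = 0.05),
                 "failure")
  expect_true(anyNA(mm))
})
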