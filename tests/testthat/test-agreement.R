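test_that("Bland-Altman bias and limits of agreement", {
  a <- c(10, 12, 9, 14)
  ba0 <- bland_altman(a, a)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  ## d = {-1, +1}: bias 0, LOA = +-1.96 sqrt(2)
  ba <- bland_altman(c(9, 11), c(10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  ## translation: adding c to a shifts bias, leaves LOA width unchanged
  b <- c(11, 13, 8, 15)
  ba1 <- bland_altman(a, b)
  ba2 <- bland_altman(a + 5, b)
  expect_equal(ba2$bias, ba1$bias + 5)
  expect_equal(ba2$loa_high - ba2$loa_low, ba1$loa_high - ba1$loa_low)
  ## pair order permutation invariance
  o <- c(3, 1, 4, 2)
  ba3 <- bland_altman(a[o], b[o])
  expect_equal(ba3$bias, ba1$bias)
  expect_equal(ba3$loa_low, ba1$loa_low)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("paired t-test matches the closed form and base R", {
  ## large separation
  set.seed(1)
  a <- rnorm(10, 100, 1)
  expect_lt(paired_t_test(a + 50, a), 0.001)
  ## symmetric differences: t = 0, p = 1
  expect_equal(paired_t_test(c(9, 11), c(10, 10)), 1)
  ## d = 1..5: matches t CDF oracle and stats::t.test
  a5 <- c(1, 2, 3, 4, 5); b5 <- rep(0, 5)
  tstat <- 3 / (stats::sd(a5) / sqrt(5))
  expect_equal(paired_t_test(a5, b5), 2 * stats::pt(-abs(tstat), 4),
               tolerance = 1e-12)
  expect_equal(paired_t_test(a5, b5),
               stats::t.test(a5, b5, paired = TRUE)$p.value,
               tolerance = 1e-12)
  ## zero-variance zero-mean convention
  expect_equal(paired_t_test(c(1, 2), c(1, 2)), 1)
})

test_that("ICC(2,1) agrees with the ANOVA mean-squares oracle", {
  set.seed(11)
  a <- rnorm(20, 100, 15); b <- a + rnorm(20, 2, 5)
  r <- icc_agreement(a, b)
  ## independent oracle: mean squares from aov on the long layout
  long <- data.frame(score = c(a, b),
                     subj = factor(rep(1:20, 2)),
                     meth = factor(rep(1:2, each = 20)))
  ms <- summary(stats::aov(score ~ subj + meth, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 20)
  expect_equal(r$icc, icc_oracle, tolerance = 1e-12)
  ## frozen cross-check against an independent reference implementation
  expect_equal(r$icc, 0.965036, tolerance = 1e-5)
  expect_equal(r$ci_low, 0.914963, tolerance = 1e-4)
  expect_equal(r$ci_high, 0.985947, tolerance = 1e-4)
})

test_that("ICC limits: identity, shuffling, degenerate input", {
  a <- c(3, 7, 5, 9, 11, 2, 8)
  r <- icc_agreement(a, a)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  set.seed(42)
  big <- rnorm(400, 50, 10)
  r2 <- icc_agreement(big, sample(big))
  expect_lt(abs(r2$icc), 0.15)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("ICC decreases monotonically with added noise", {
  set.seed(13)
  a <- rnorm(60, 100, 15)
  iccs <- vapply(c(1, 5, 15, 40), function(sig) {
    icc_agreement(a, a + rnorm(60, 0, sig))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("ICC banding follows the published cutoffs", {
  expect_equal(icc_band(0.95), "excellent")
  expect_equal(icc_band(0.71), "good")
  expect_equal(icc_band(0.56), "moderate")
  expect_equal(icc_band(c(0.91, 0.9, 0.6, 0.59)),
               c("excellent", "good", "good", "moderate"))
})

test_that("MAE basics and the bias inequality", {
  a <- c(1, 2, 3); expect_equal(mean_absolute_error(a, a), 0)
  expect_equal(mean_absolute_error(c(0, 4), c(2, 2)), 2)
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    expect_gte(mean_absolute_error(x, y) + 1e-12,
               abs(bland_altman(x, y)$bias))
  }
  ## permutation invariance
  x <- rnorm(8); y <- rnorm(8); o <- sample(8)
  expect_equal(mean_absolute_error(x[o], y[o]), mean_absolute_error(x, y))
})

test_that("agreement summary bundles the statistics coherently", {
  set.seed(14)
  a <- rnorm(15, 100, 20); b <- a + rnorm(15, 1, 4)
  s <- agreement_summary(a, b, parameter = "net_flow")
  expect_lte(s$loa_low, s$bias); expect_gte(s$loa_high, s$bias)
  expect_gte(s$mae, abs(s$bias))
  expect_true(s$icc >= -1 && s$icc <= 1)
  td <- tidy(s)
  expect_equal(td$estimate[td$term == "bias"], s$bias)
  gl <- glance(s)
  expect_equal(gl$parameter, "net_flow")
  expect_equal(gl$icc, s$icc)
})

test_that("blur metric orders a generated blur ladder", {
  set.seed(15)
  n <- 64
  ## sharp edge/checkerboard image
  img <- outer(seq_len(n), seq_len(n),
               function(i, j) (i %/% 8 + j %/% 8) %% 2) * 1.0
  gauss_blur <- function(x, sigma) {
    t <- seq(-12, 12)
    k <- exp(-t^2 / (2 * sigma^2)); k <- k / sum(k)
    x <- spiralflow:::apply_1d_kernel(x, k, 1)
    spiralflow:::apply_1d_kernel(x, k, 2)
  }
  ladder <- list(img, gauss_blur(img, 1), gauss_blur(img, 2.5),
                 gauss_blur(img, 5))
  vals <- vapply(ladder, blur_metric, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 0.4)
  ## constant image convention
  expect_equal(blur_metric(matrix(5, 16, 16)), 1)
  expect_error(blur_metric(matrix(1, 4, 4)), "8x8")
})
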