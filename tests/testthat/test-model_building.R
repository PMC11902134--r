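test_that("noiseless log-polynomial data are recovered to machine precision", {
  x <- seq(6, 30, length.out = 60)
  y <- exp(3.2 - 0.02 * x + 0.001 * x^2)
  m <- fit_log_polynomial(x, y, max_degree = 3)
  expect_equal(m$degree, 2)
  expect_equal(unname(m$coeffs), c(3.2, -0.02, 0.001), tolerance = 1e-10)
  expect_equal(m$r_squared, 1)
  expect_equal(m$bf_range_fit, c(6, 30))
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  x <- seq(5, 25, length.out = 40)
  m_const <- fit_log_polynomial(x, rep(24, 40))
  expect_equal(m_const$degree, 1)
  expect_lt(abs(m_const$coeffs[["c1"]]), 1e-12)
  expect_equal(m_const$r_squared, 0)

  expect_error(fit_log_polynomial(x[1:4], exp(x[1:4])), "n > max_degree")
  expect_error(fit_log_polynomial(rep(10, 40), 20 + x), "distinct")
  expect_error(fit_log_polynomial(x, c(-1, x[-1])), "positive")
})

test_that("default synthetic cohort fits near the calibrated R-squared", {
  coh <- generate_cohort(cohort_config(seed = 8))
  m <- fit_log_polynomial(coh$bf_pct, coh$bmi)
  expect_lt(abs(m$r_squared - 0.4447), 0.08)
})

test_that("predict_bmi is the exact antilog of the polynomial", {
  m <- adiposity_model(c(3.2, -0.02, 0.001), bf_range_fit = c(0, 35))
  expect_equal(predict_bmi(m, 0), exp(3.2))
  expect_equal(round(predict_bmi(m, 0), 2), 24.53)
  x <- c(8, 13.1, 21, 26)
  expect_equal(log(predict_bmi(m, x)), 3.2 - 0.02 * x + 0.001 * x^2,
               tolerance = 1e-15)
  # vectorisation contract
  expect_equal(predict_bmi(m, x),
               vapply(x, function(xi) predict_bmi(m, xi), numeric(1)))
})

test_that("predictions outside the fitted range carry warnings", {
  x <- seq(8, 24, length.out = 40)
  m <- fit_log_polynomial(x, exp(3.2 - 0.02 * x + 0.001 * x^2))
  expect_silent(predict_bmi(m, 20))
  expect_warning(predict_bmi(m, 25.5), "guard")
  expect_warning(predict_bmi(m, 30), "heavy extrapolation")
  # warning-carrying result, never an error
  expect_equal(suppressWarnings(predict_bmi(m, 30)),
               exp(3.2 - 0.02 * 30 + 0.001 * 900))
})

test_that("CUSUM: exact linear data give a zero statistic and no rejection", {
  x <- seq(5, 30, length.out = 50)
  res <- cusum_linearity_test(x, 2 + 0.4 * x, seed = 1)
  expect_equal(res$statistic, 0)
  expect_false(res$reject_linearity)
})

test_that("CUSUM statistic is invariant under affine rescaling of y", {
  set.seed(31)
  x <- runif(80, 5, 30)
  y <- 1 + 0.3 * x + rnorm(80, 0, 0.5)
  a <- cusum_linearity_test(x, y, n_sims = 100, seed = 9)
  b <- cusum_linearity_test(x, 3.7 * y - 11, n_sims = 100, seed = 9)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$threshold, b$threshold, tolerance = 1e-12)
})

test_that("CUSUM rejects the curvilinear adiposity relation with small noise", {
  # oracle-checked: empirical rejection rate is 100% over 100 replicates at
  # n_sims = 400; asserted here on a 20-replicate slice (full loop in the
  # acceptance suite)
  cf <- cohort_config()$ln_coeffs
  rej <- vapply(1:20, function(s) {
    set.seed(s)
    x <- generate_cohort(cohort_config(seed = s))$bf_pct
    y <- exp(cf[1] + cf[2] * x + cf[3] * x^2) + rnorm(length(x), 0, 0.5)
    cusum_linearity_test(x, y, n_sims = 300, seed = s)$reject_linearity
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("CUSUM preconditions are enforced", {
  expect_error(cusum_linearity_test(1:10, rnorm(10)), "n >= 20")
  expect_error(cusum_linearity_test(rep(1:4, 6), rnorm(24)), "distinct")
  expect_error(cusum_linearity_test(1:30, rnorm(29)), "length")
})

test_that("fit recovers generating coefficients without systematic bias", {
  cf <- cohort_config()$ln_coeffs
  est <- t(vapply(1:100, function(s) {
    coh <- generate_cohort(cohort_config(seed = 400 + s))
    unname(fit_log_polynomial(coh$bf_pct, coh$bmi, degree = 2)$coeffs)
  }, numeric(3)))
  for (j in 1:3) {
    bias <- mean(est[, j]) - cf[j]
    mc_se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(bias), 2 * mc_se)
  }
})
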