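# Model fitting and performance measures.

test_that("logistic MLE recovers known coefficients and flags pathologies", {
  spec <- scenario_spec(0.3, 0.75, 4)
  model <- cached_model(spec, "small_0.3_0.75")
  d <- simulate_dataset(model, spec, n = 2e5, seed = 31)
  fit <- fit_logistic_mle(d$X, d$y)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  # within 3 SE of the truth (SE from the information at the truth, roughly
  # sqrt(1 / (n * phi * (1-phi))) per standardized predictor)
  se_rough <- 3 / sqrt(2e5 * 0.3 * 0.7 / 4)
  expect_lt(max(abs(fit$coef - c(model$beta0, model$beta))), se_rough)
  expect_lte(fit$deviance_model, fit$deviance_null)

  expect_error(fit_logistic_mle(d$X[1:5, ], rep(1, 5)), "single class")
  sep <- fit_logistic_mle(matrix(rep(c(-1, 1), each = 20), ncol = 1),
                          rep(c(0, 1), each = 20))
  expect_true(sep$separation_flag)
})

test_that("calibration slope identifies calibrated and rescaled predictors", {
  set.seed(41)
  eta <- rnorm(1e5, -1, 1.5)
  y <- rbinom(1e5, 1, plogis(eta))
  expect_equal(calibration_slope(eta, y), 1, tolerance = 0.03)
  # doubling the linear predictor halves the slope
  expect_equal(calibration_slope(2 * eta, y), 0.5, tolerance = 0.02)
  expect_error(calibration_slope(rep(1, 100), rbinom(100, 1, 0.5)), "constant")
})

test_that("overfit small-sample models show slopes below 1 on validation data", {
  spec <- scenario_spec(0.3, 0.8, 8)
  model <- cached_model(spec, "small_0.3_0.8")
  set.seed(42)
  slopes <- replicate(40, {
    d <- simulate_dataset(model, spec, n = 150)
    f <- fit_logistic_mle(d$X, d$y)
    v <- simulate_validation(model, spec, n_val = 5000)
    calibration_slope(drop(f$coef[1] + v$X %*% f$coef[-1]), v$y)
  })
  expect_lt(mean(slopes) + 3 * mcse(slopes), 1)
})

test_that("rank-based c-statistic equals the all-pairs estimator", {
  expect_identical(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(51)
  for (rep in 1:3) {
    pi_hat <- round(runif(200), 2) # rounding forces ties
    y <- rbinom(200, 1, 0.4)
    expect_identical(c_statistic(pi_hat, y), cstat_bruteforce(pi_hat, y))
  }
  expect_error(c_statistic(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("c-statistic is invariant to strictly increasing transforms", {
  set.seed(52)
  pi_hat <- runif(300); y <- rbinom(300, 1, pi_hat)
  expect_identical(c_statistic(pi_hat, y), c_statistic(qlogis(pi_hat), y))
  expect_identical(c_statistic(pi_hat, y), c_statistic(pi_hat^3, y))
})

test_that("MAPE identities and oracle equivalence", {
  p <- runif(100)
  expect_identical(mape(p, p), 0)
  expect_equal(mape(pmin(p, 0.9) + 0.05, pmin(p, 0.9)), 0.05)
  q <- runif(100)
  expect_identical(mape(p, q), sum(abs(p - q)) / 100)
  expect_error(mape(p, q[1:50]), "same length")
})

test_that("RMSD of the calibration slope decomposes into bias and variance", {
  expect_identical(rmsd_cs(rep(1, 10)), 0)
  expect_equal(rmsd_cs(c(0.8, 1.2)), 0.2)
  cs <- c(0.7, 0.85, 0.9, 1.05, 1.1)
  pop_var <- mean((cs - mean(cs))^2)
  expect_equal(rmsd_cs(cs)^2, (mean(cs) - 1)^2 + pop_var)
})

test_that("Monte Carlo standard error scales as 1/sqrt(n_sim)", {
  expect_identical(mcse(rep(2, 50)), 0)
  x <- rnorm(400)
  expect_equal(mcse(x), sd(x) / 20)
  expect_equal(mcse(rep(x, 4)) / mcse(x), 1 / 2, tolerance = 0.01)
})
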