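# Calibration of the normal linear predictor to (prevalence, c-statistic)
# and the Cox-Snell R^2 mappings.

test_that("induced prevalence matches degenerate cases and a Monte Carlo oracle", {
  expect_equal(induced_prevalence(0, 0), 0.5)
  expect_equal(induced_prevalence(qlogis(0.1), 0), 0.1)

  set.seed(101)
  draws <- plogis(0 + 2 * rnorm(1e6))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(induced_prevalence(0, 2) - mean(draws)), 3 * mc_se)

  expect_error(induced_prevalence(Inf, 1))
  expect_error(induced_prevalence(0, -0.5))
})

test_that("induced c-statistic handles ties, agrees with simulation, grows with signal", {
  expect_identical(induced_cstatistic(-1.3, 0), 0.5)
  expect_identical(induced_cstatistic(2.0, 0), 0.5)

  # MC oracle: c-statistic of the true LP on a large sample from the model
  set.seed(202)
  n <- 1e6
  eta <- rnorm(n) # mu = 0, sigma = 1
  y <- rbinom(n, 1, plogis(eta))
  expect_lt(abs(induced_cstatistic(0, 1) - c_statistic(eta, y)), 0.002)

  expect_gt(induced_cstatistic(-1, 2), induced_cstatistic(-1, 1))
  expect_gt(induced_cstatistic(0, 1.5), induced_cstatistic(0, 0.75))
})

test_that("solve_lp_distribution is self-consistent and recovers the null limit", {
  ms <- solve_lp_distribution(0.1, 0.85)
  expect_lt(abs(induced_prevalence(ms[["mu"]], ms[["sigma"]]) - 0.1), 1e-6)
  expect_lt(abs(induced_cstatistic(ms[["mu"]], ms[["sigma"]]) - 0.85), 1e-6)

  near_null <- solve_lp_distribution(0.5, 0.505)
  expect_lt(abs(near_null[["mu"]]), 0.01)
  expect_lt(near_null[["sigma"]], 0.05)
})

test_that("calibrated scenario round-trips through a large simulated sample", {
  spec <- example_spec()
  model <- example_model()
  d <- simulate_dataset(model, spec, n = 1e6, seed = 404)
  expect_lt(abs(mean(d$y) - 0.174), 0.002)
  expect_lt(abs(c_statistic(d$lp_true, d$y) - 0.89), 0.003)
})

test_that("analytic R2_CS matches its closed-form limits and the large-sample estimate", {
  # no discrimination => no explained variation
  expect_lt(approx_r2cs(0.3, 0.505), 1e-3)
  # frozen quadrature values for the headline scenario
  expect_equal(approx_r2cs(0.174, 0.89), 0.2878, tolerance = 2e-3)
  expect_equal(r2cs_from_cstat(0.174, 0.89), 0.2910, tolerance = 2e-3)
  # monotone in model strength
  r2 <- vapply(c(0.6, 0.7, 0.8, 0.9), function(cc) approx_r2cs(0.3, cc), numeric(1))
  expect_true(all(diff(r2) > 0))
  # the two analytic conversions are close
  expect_lt(abs(approx_r2cs(0.1, 0.85) - r2cs_from_cstat(0.1, 0.85)), 0.01)
  # and both agree with the one-million-observation simulated fit
  r2_sim <- r2cs_from_large_sample(ref_spec(0.1, 0.85), N = 1e6, seed = 7)
  expect_lt(abs(approx_r2cs(0.1, 0.85) - r2_sim), 0.01)
})

test_that("coefficients reproduce the requested linear-predictor variance", {
  # single active predictor: f equals sigma directly
  spec1 <- scenario_spec(0.2, 0.8, 4, relative_strengths = c(1, 0, 0, 0))
  m1 <- coefficients_from_lp(spec1, mu = -1, sigma = 0.8)
  expect_equal(m1$scale_f, 0.8)
  expect_equal(m1$beta, c(0.8, 0, 0, 0))
  expect_equal(m1$beta0, -1)

  # reference correlated structure: empirical Var(beta' x) within 1% of sigma^2
  spec2 <- ref_spec(0.1, 0.85)
  m2 <- cached_model(spec2, "ref_0.1_0.85")
  d2 <- simulate_dataset(m2, spec2, n = 5e5, seed = 11)
  expect_equal(var(d2$lp_true), m2$sigma^2, tolerance = 0.01)

  # binary predictors: Bernoulli variances replace the correlation matrix
  spec3 <- scenario_spec(0.3, 0.75, 6, predictor_kind = "binary")
  ms3 <- solve_lp_distribution(0.3, 0.75)
  m3 <- coefficients_from_lp(spec3, ms3[["mu"]], ms3[["sigma"]])
  d3 <- simulate_dataset(m3, spec3, n = 5e5, seed = 12)
  expect_equal(var(d3$lp_true), m3$sigma^2, tolerance = 0.01)
  expect_equal(mean(d3$lp_true), m3$mu, tolerance = 0.02)

  # requesting signal with all-zero strengths is rejected at spec construction
  expect_error(scenario_spec(0.3, 0.75, 3, relative_strengths = c(0, 0, 0)))
})
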