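# Time-to-event extension.

test_that("exponential survival times and administrative censoring behave as specified", {
  scen <- survival_scenario(0.75, n_params = 4, relative_strengths = rep(1, 4))
  null_model <- coefficients_from_lp(scen$spec, mu = 0, sigma = 0)

  # eta = 0: observed times are Exponential(baseline_rate)
  d0 <- simulate_survival(null_model, scen$spec, n = 2e4, baseline_rate = 0.25,
                          seed = 71)
  expect_identical(d0$uncensored_prop, 1)
  expect_gt(ks.test(d0$time, pexp, rate = 0.25)$p.value, 1e-3)

  # no censoring when censor_time is infinite
  d1 <- simulate_survival(scen$model, scen$spec, 5000, baseline_rate = 0.25,
                          censor_time = Inf, seed = 72)
  expect_identical(d1$uncensored_prop, 1)

  # proportional hazards: higher linear predictor, stochastically shorter times
  expect_lt(cor(d1$lp_true, d1$time, method = "spearman"), -0.2)
})

test_that("censoring time calibration hits the target event proportion", {
  scen <- survival_scenario(0.8, n_params = 4, relative_strengths = rep(1, 4))
  null_model <- coefficients_from_lp(scen$spec, mu = 0, sigma = 0)

  # eta = 0, target 0.5: the exponential median
  expect_equal(calibrate_censor_time(null_model, 0.2, 0.5), log(2) / 0.2,
               tolerance = 1e-6)
  expect_identical(calibrate_censor_time(scen$model, 0.2, 1), Inf)
  expect_error(calibrate_censor_time(scen$model, 0.2, 0), "\\(0, 1\\]")

  # sigma > 0, target 0.1: verified against a large Monte Carlo draw
  ct <- calibrate_censor_time(scen$model, 0.2, 0.1)
  d <- simulate_survival(scen$model, scen$spec, 1e6, baseline_rate = 0.2,
                         censor_time = ct, seed = 73)
  expect_lt(abs(d$uncensored_prop - 0.1), 0.005)
})

test_that("Harrell c-index matches the brute-force comparable-pairs oracle", {
  # perfectly anti-monotone risk vs time, no censoring
  expect_identical(harrell_cindex(10:1, 1:10, rep(1, 10)), 1)
  set.seed(74)
  expect_equal(harrell_cindex(rnorm(4000), rexp(4000), rep(1, 4000)), 0.5,
               tolerance = 0.03)
  for (rep in 1:3) {
    lp <- round(rnorm(150), 1) # ties in the score
    time <- rexp(150, exp(lp))
    event <- as.integer(time <= quantile(time, 0.6))
    time <- pmin(time, quantile(time, 0.6))
    expect_equal(harrell_cindex(lp, time, event),
                 cindex_bruteforce(lp, time, event), tolerance = 1e-12)
  }
  expect_error(harrell_cindex(c(1, 2), c(5, 6), c(0, 0)), "comparable")
})

test_that("survival calibration slope identifies true and rescaled predictors", {
  scen <- survival_scenario(0.8, n_params = 4, relative_strengths = rep(1, 4))
  d <- simulate_survival(scen$model, scen$spec, 3e4, baseline_rate = 0.1,
                         censor_time = 15, seed = 75)
  expect_equal(survival_calibration_slope(d$lp_true, d$time, d$event), 1,
               tolerance = 0.04)
  expect_equal(survival_calibration_slope(2 * d$lp_true, d$time, d$event), 0.5,
               tolerance = 0.02)
  expect_error(survival_calibration_slope(d$lp_true, d$time, rep(0, 3e4)),
               "no events")
})

test_that("overfitting of Cox models worsens with less censoring at high c-index", {
  scen <- survival_scenario(0.85)
  # calibration-criterion sizes using the Cox-model R2 at each censoring level:
  # less censoring means more information per subject and a smaller n
  n_for <- function(u)
    rvs1_n(12, 0.9, r2cs = r2cs_cox_large_sample(scen, 0.1, u, N = 2e5, seed = 5))$n
  lo <- evaluate_performance_survival(scen, n_for(0.3), n_sim = 200,
                                      n_val = 6000, target_uncensored = 0.3,
                                      seed = 76)
  hi <- evaluate_performance_survival(scen, n_for(0.9), n_sim = 200,
                                      n_val = 6000, target_uncensored = 0.9,
                                      seed = 76)
  expect_lt(hi$mean_cs, lo$mean_cs)   # worse underestimation with more events
  expect_lt(hi$mean_cs + 3 * hi$mcse_cs, 0.9) # target expected CS is missed
  expect_lt(lo$mean_cs + 3 * lo$mcse_cs, 0.9)
})

test_that("survival calibration slope near target at moderate strength and heavy censoring", {
  scen <- survival_scenario(0.65)
  n <- rvs1_n(12, 0.9,
              r2cs = r2cs_cox_large_sample(scen, 0.1, 0.5, N = 2e5, seed = 5))$n
  perf <- evaluate_performance_survival(scen, n, n_sim = 150, n_val = 6000,
                                        target_uncensored = 0.5, seed = 77)
  expect_lt(abs(perf$mean_cs - 0.9), 0.05)
})
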