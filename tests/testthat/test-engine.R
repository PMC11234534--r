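# Monte Carlo engine: distribution of performance at a fixed sample size.

test_that("engine output is reproducible and internally consistent", {
  spec <- scenario_spec(0.3, 0.75, 6)
  model <- cached_model(spec, "small_0.3_0.75_p6")
  p1 <- evaluate_performance(spec, n = 300, n_sim = 60, n_val = 3000,
                             seed = 8, model = model)
  p2 <- evaluate_performance(spec, n = 300, n_sim = 60, n_val = 3000,
                             seed = 8, model = model)
  expect_identical(p1$cs, p2$cs)
  expect_identical(p1$mape, p2$mape)

  expect_length(p1$cs, 60)
  expect_equal(p1$mcse_cs, sd(p1$cs) / sqrt(60))
  expect_equal(p1$rmsd_cs, sqrt(mean((p1$cs - 1)^2)))
  expect_gte(p1$p_cs_below_08, 0)
  expect_lte(p1$p_cs_below_09, 1)
  expect_true(all(p1$mape <= 1))
  expect_equal(p1$true_cstat, 0.75, tolerance = 1e-6)
})

test_that("the two validation sampling routes agree in distribution", {
  spec <- scenario_spec(0.3, 0.75, 6)
  model <- cached_model(spec, "small_0.3_0.75_p6")
  lp <- evaluate_performance(spec, n = 300, n_sim = 120, n_val = 4000,
                             seed = 9, model = model, val_method = "lp")
  full <- evaluate_performance(spec, n = 300, n_sim = 120, n_val = 4000,
                               seed = 10, model = model, val_method = "full")
  expect_lt(abs(lp$mean_cs - full$mean_cs),
            3 * sqrt(lp$mcse_cs^2 + full$mcse_cs^2))
  expect_lt(abs(lp$mean_mape - full$mean_mape),
            3 * sqrt(lp$mcse_mape^2 + full$mcse_mape^2))
})

test_that("performance approaches the true model as n grows", {
  spec <- scenario_spec(0.3, 0.75, 6)
  model <- cached_model(spec, "small_0.3_0.75_p6")
  small <- evaluate_performance(spec, 200, n_sim = 80, n_val = 4000,
                                seed = 12, model = model)
  large <- evaluate_performance(spec, 8000, n_sim = 80, n_val = 4000,
                                seed = 12, model = model)
  expect_lt(abs(large$mean_cs - 1), abs(small$mean_cs - 1))
  expect_lt(large$mean_mape, small$mean_mape)
  expect_gt(large$mean_cs, 0.97)
  expect_lt(small$mean_cs, 0.92)
})

test_that("true model is calibrated: expected slope 1 on its own population", {
  spec <- scenario_spec(0.2, 0.8, 5)
  model <- cached_model(spec, "small_0.2_0.8")
  set.seed(13)
  slopes <- replicate(80, {
    v <- simulate_validation(model, spec, n_val = 4000)
    calibration_slope(v$lp_true, v$y)
  })
  expect_lt(abs(mean(slopes) - 1), 3 * mcse(slopes))
})

test_that("heuristic shrinkage tracks the mean CS at modest strength, not at high", {
  n <- 620
  # modest strength: heuristic approximates the simulated expected CS
  spec_lo <- main_study_spec(0.3, 0.7)
  model_lo <- cached_model(spec_lo, "ref_0.3_0.7")
  set.seed(14)
  s_heur_lo <- replicate(120, {
    d <- simulate_dataset(model_lo, spec_lo, n)
    f <- fit_logistic_mle(d$X, d$y)
    heuristic_shrinkage(f$deviance_null - f$deviance_model, 12)
  })
  perf_lo <- evaluate_performance(spec_lo, n, n_sim = 120, n_val = 8000,
                                  seed = 14, model = model_lo)
  expect_lt(abs(mean(s_heur_lo) - perf_lo$mean_cs), 0.03)

  # high strength: the heuristic promises too little shrinkage
  spec_hi <- main_study_spec(0.3, 0.9)
  model_hi <- cached_model(spec_hi, "ref_0.3_0.9")
  n_hi <- rvs1_n(12, 0.9, prevalence = 0.3, c_statistic = 0.9)$n
  set.seed(15)
  s_heur_hi <- replicate(120, {
    d <- simulate_dataset(model_hi, spec_hi, n_hi)
    f <- fit_logistic_mle(d$X, d$y)
    heuristic_shrinkage(f$deviance_null - f$deviance_model, 12)
  })
  perf_hi <- evaluate_performance(spec_hi, n_hi, n_sim = 120, n_val = 8000,
                                  seed = 15, model = model_hi)
  expect_gt(mean(s_heur_hi), perf_hi$mean_cs + 0.03)
})

test_that("an undersized sample triggers the low-events warning", {
  spec <- scenario_spec(0.1, 0.7, 12)
  model <- cached_model(spec, "small_0.1_0.7")
  expect_warning(
    evaluate_performance(spec, n = 150, n_sim = 10, n_val = 1000,
                         seed = 16, model = model),
    "below 2p")
})
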