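## Monte Carlo engine: the distribution of predictive performance at a given
## development sample size.

#' Evaluate predictive performance at a development sample size
#'
#' For each of `n_sim` replicates: simulate a development dataset of size
#' `n` from the calibrated scenario, fit the logistic model by maximum
#' likelihood, and measure the fitted model's calibration slope, c-statistic
#' and MAPE on a fresh validation sample of size `n_val` from the same
#' population. Summaries include Monte Carlo standard errors, the RMSD of
#' the calibration slope from 1, the probability of substantial overfitting
#' (CS < 0.8, also CS < 0.9), and the probability that the c-statistic is
#' within 0.02 of the true model's c-statistic.
#'
#' Replicates whose development fit has a single-class outcome, fails to
#' converge, or shows quasi-separation are redrawn from the replicate's own
#' substream; the number of redraws is recorded and a warning is raised if
#' they exceed 1% of `n_sim`.
#'
#' For continuous predictors the validation pair \eqn{(\eta, \hat\eta)}
#' given the fitted coefficients is exactly bivariate normal under the
#' multivariate-normal predictor model, so by default (`val_method = "lp"`)
#' validation draws are taken directly from that joint distribution, which
#' is distributionally identical to materialising the predictor matrix and
#' considerably faster. `val_method = "full"` simulates the full predictor
#' matrix and is the default (and only) route for binary predictors.
#'
#' @param spec A [scenario_spec()].
#' @param n Development sample size.
#' @param n_sim Number of simulation replicates (default 1000;
#'   study-replication convention is 2000).
#' @param n_val Validation sample size (default 25,000; study-replication
#'   convention is 100,000).
#' @param seed Master seed; spawns independent development and validation
#'   substreams per replicate, so results are reproducible and evaluations
#'   at different `n` under the same seed share common random numbers.
#' @param model Optional pre-calibrated `lp_model` (avoids re-solving when
#'   evaluating many sample sizes).
#' @param val_method `"auto"` (lp sampling for continuous predictors, full
#'   simulation for binary), `"lp"`, or `"full"`.
#' @return A `perf_distribution`: per-replicate metrics plus summaries
#'   (`mean_cs`, `sd_cs`, `mcse_cs`, `rmsd_cs`, `p_cs_below_08`,
#'   `p_cs_below_09`, `mean_mape`, `mcse_mape`, `mean_cstat`,
#'   `p_cstat_within_002`, `true_cstat`, `n_redrawn`).
#' @examples
#' \donttest{
#' spec <- scenario_spec(0.3, 0.75, 12)
#' evaluate_performance(spec, n = 620, n_sim = 200, n_val = 5000, seed = 7)
#' }
#' @export
evaluate_performance <- function(spec, n, n_sim = 1000, n_val = 25000,
                                 seed = 1L, model = NULL,
                                 val_method = c("auto", "lp", "full")) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 2, n_sim >= 2, n_val >= 100)
  val_method <- match.arg(val_method)
  if (val_method == "auto")
    val_method <- if (spec$predictor_kind == "continuous") "lp" else "full"
  if (val_method == "lp" && spec$predictor_kind != "continuous")
    stop("val_method = \"lp\" requires continuous predictors", call. = FALSE)
  if (is.null(model)) model <- calibrate_scenario(spec)
  p <- spec$n_params
  if (n * spec$prevalence < 2 * p)
    warning("expected number of events (", round(n * spec$prevalence, 1),
            ") is below 2p; fits may be unstable", call. = FALSE)
  dev_seeds <- spawn_seeds(seed, n_sim)
  val_seeds <- spawn_seeds(seed + 1L, n_sim)
  true_c <- if (spec$predictor_kind == "continuous")
    induced_cstatistic(model$mu, model$sigma) else spec$c_statistic
  R <- spec$correlation
  Rb <- R %*% model$beta
  cs <- cstat <- mp <- numeric(n_sim)
  n_redrawn <- 0L
  for (i in seq_len(n_sim)) {
    set.seed(dev_seeds[i])
    fit <- NULL
    for (attempt in seq_len(100)) {
      d <- simulate_dataset(model, spec, n)
      if (sum(d$y) > 0 && sum(d$y) < n) {
        f <- fit_logistic_mle(d$X, d$y)
        if (f$converged && !f$separation_flag) { fit <- f; break }
      }
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(fit))
      stop("development fit failed in 100 consecutive redraws (replicate ", i,
           "); the scenario/sample size is too extreme for MLE", call. = FALSE)
    b0h <- fit$coef[1]; bh <- fit$coef[-1]
    set.seed(val_seeds[i])
    if (val_method == "lp") {
      v2 <- drop(crossprod(bh, R %*% bh))
      cv <- drop(crossprod(bh, Rb))
      a <- cv / model$sigma
      b <- sqrt(max(v2 - a^2, 0))
      z1 <- stats::rnorm(n_val); z2 <- stats::rnorm(n_val)
      lp_true <- model$mu + model$sigma * z1
      lp_hat <- b0h + a * z1 + b * z2
      pi_true <- expit(lp_true)
      y <- stats::rbinom(n_val, 1L, pi_true)
    } else {
      v <- simulate_dataset(model, spec, n_val)
      lp_hat <- drop(b0h + v$X %*% bh)
      pi_true <- v$pi_true
      y <- v$y
    }
    cs[i] <- fit_slope(lp_hat, y)[2]
    cstat[i] <- c_statistic(lp_hat, y)
    mp[i] <- mean(abs(expit(lp_hat) - pi_true))
  }
  if (n_redrawn > 0.01 * n_sim)
    warning(n_redrawn, " development fits were redrawn (> 1% of n_sim)", call. = FALSE)
  structure(list(
    n = n, n_sim = n_sim, n_val = n_val, seed = seed,
    cs = cs, cstat = cstat, mape = mp,
    mean_cs = mean(cs), sd_cs = stats::sd(cs), mcse_cs = mcse(cs),
    rmsd_cs = rmsd_cs(cs),
    p_cs_below_08 = mean(cs < 0.8), p_cs_below_09 = mean(cs < 0.9),
    mean_mape = mean(mp), mcse_mape = mcse(mp),
    mean_cstat = mean(cstat),
    p_cstat_within_002 = mean(abs(cstat - true_c) <= 0.02),
    true_cstat = true_c,
    n_redrawn = n_redrawn,
    spec = spec, model = model, val_method = val_method),
    class = "perf_distribution")
}

#' @export
print.perf_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Performance at n = %d (%d replicates, n_val = %d)\n",
              x$n, x$n_sim, x$n_val))
  cat(sprintf("  mean CS    %.*f (MCSE %.4f, SD %.4f, RMSD from 1: %.4f)\n",
              digits, x$mean_cs, x$mcse_cs, x$sd_cs, x$rmsd_cs))
  cat(sprintf("  P(CS<0.8)  %.3f   P(CS<0.9) %.3f\n",
              x$p_cs_below_08, x$p_cs_below_09))
  cat(sprintf("  mean MAPE  %.*f (MCSE %.5f)\n", digits, x$mean_mape, x$mcse_mape))
  cat(sprintf("  mean c-hat %.*f (true c %.4f, P(|c-hat - c| <= 0.02) = %.3f)\n",
              digits, x$mean_cstat, x$true_cstat, x$p_cstat_within_002))
  if (x$n_redrawn > 0)
    cat(sprintf("  %d development fits redrawn\n", x$n_redrawn))
  invisible(x)
}
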