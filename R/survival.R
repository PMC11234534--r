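## Time-to-event extension: exponential survival DGM with administrative
## censoring, Harrell's c-index, and the survival calibration slope.

#' Calibrate the linear-predictor SD to a target concordance (c-index)
#'
#' Under a proportional-hazards model with exponential survival times and a
#' normal linear predictor \eqn{\eta \sim N(0, \sigma^2)}, the censoring-free
#' concordance of the true model has the closed integral form
#' \eqn{c = E[\mathrm{expit}(|\Delta|)]} with
#' \eqn{\Delta \sim N(0, 2\sigma^2)} (for an exponential pair, the earlier
#' event occurs in subject i with probability expit(\eqn{\eta_i - \eta_j})).
#' The SD is solved by root-finding on that integral.
#'
#' @param c_index Target Harrell's c-index, in (0.5, 1).
#' @return The linear-predictor standard deviation.
#' @export
solve_sigma_cindex <- function(c_index) {
  stopifnot(c_index > 0.5, c_index < 1)
  cfun <- function(sigma) gh_expect(function(d) expit(abs(d)), 0, sqrt(2) * sigma) - c_index
  stats::uniroot(cfun, c(1e-8, 50), tol = 1e-10)$root
}

#' Survival scenario: coefficients for a target c-index
#'
#' Builds an `lp_model` for a time-to-event scenario: the linear-predictor
#' SD is calibrated to the target concordance with [solve_sigma_cindex()]
#' and scaled onto the predictor structure (zero mean: the baseline hazard
#' carries the scale, so there is no intercept).
#'
#' @param c_index Target Harrell's c-index of the true model.
#' @param n_params Number of predictors.
#' @param relative_strengths Non-negative relative coefficient sizes
#'   (default: the 5-true/7-noise pattern when `n_params = 12`, otherwise
#'   equal strengths).
#' @param correlation Predictor correlation matrix (default identity,
#'   matching the reference survival setting of uncorrelated predictors).
#' @return A list with the `lp_model` (`model`) and the implied
#'   `scenario_spec`-like predictor structure (`spec`).
#' @export
survival_scenario <- function(c_index, n_params = 12L,
                              relative_strengths = NULL,
                              correlation = NULL) {
  p <- as.integer(n_params)
  if (is.null(relative_strengths))
    relative_strengths <- if (p == 12L) c(0.4, 0.2, 0.2, 0.1, 0.1, rep(0, 7)) else rep(1, p)
  if (is.null(correlation)) correlation <- diag(p)
  # prevalence/c_statistic slots are placeholders: survival scenarios are
  # parameterised by c-index and censoring, not by outcome prevalence
  spec <- scenario_spec(0.5, c_index, p, relative_strengths, correlation)
  sigma <- solve_sigma_cindex(c_index)
  model <- coefficients_from_lp(spec, mu = 0, sigma = sigma)
  list(model = model, spec = spec, c_index = c_index)
}

#' Simulate exponential survival data with administrative censoring
#'
#' Survival times are generated from the proportional-hazards model with
#' constant baseline hazard, \eqn{T_i \sim
#' \mathrm{Exponential}(\lambda_0 e^{\eta_i})}, and administratively
#' censored at `censor_time`.
#'
#' @param model An `lp_model` (see [survival_scenario()]).
#' @param spec The matching predictor structure (`scenario_spec`).
#' @param n Number of observations.
#' @param baseline_rate Constant baseline hazard \eqn{\lambda_0 > 0}.
#' @param censor_time Administrative censoring time (may be `Inf`).
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @return A `survival_dataset`: `X`, observed `time`, `event` indicator
#'   (1 = uncensored), `lp_true`, `censor_time` and `uncensored_prop`.
#' @export
simulate_survival <- function(model, spec, n, baseline_rate, censor_time = Inf,
                              seed = NULL) {
  stopifnot(inherits(model, "lp_model"), n >= 1, baseline_rate > 0, censor_time > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$n_params
  X <- matrix(stats::rnorm(n * p), n, p)
  if (max(abs(spec$correlation - diag(p))) > 0) X <- X %*% chol(spec$correlation)
  lp <- drop(model$beta0 + X %*% model$beta)
  t_raw <- stats::rexp(n, rate = baseline_rate * exp(lp))
  event <- as.integer(t_raw <= censor_time)
  structure(list(X = X, time = pmin(t_raw, censor_time), event = event,
                 lp_true = lp, censor_time = censor_time,
                 uncensored_prop = mean(event)),
            class = "survival_dataset")
}

#' Censoring time for a target proportion of observed events
#'
#' Solves for the administrative censoring time at which the marginal
#' probability of observing the event, \eqn{P(T \le t) = 1 -
#' E_\eta[\exp(-\lambda_0 e^\eta t)]} (computed by Gauss-Hermite quadrature
#' over the normal linear predictor), equals `target_uncensored`.
#'
#' @inheritParams simulate_survival
#' @param target_uncensored Desired proportion of uncensored observations,
#'   in (0, 1\]; a target of 1 returns `Inf` (no censoring).
#' @return The censoring time.
#' @export
calibrate_censor_time <- function(model, baseline_rate, target_uncensored) {
  stopifnot(inherits(model, "lp_model"), baseline_rate > 0)
  if (!is.numeric(target_uncensored) || target_uncensored <= 0 || target_uncensored > 1)
    stop("`target_uncensored` must lie in (0, 1]", call. = FALSE)
  if (target_uncensored == 1) return(Inf)
  p_event <- function(logt)
    1 - gh_expect(function(e) exp(-baseline_rate * exp(e) * exp(logt)),
                  model$mu, model$sigma)
  stats::uniroot(function(lt) p_event(lt) - target_uncensored,
                 c(-40, 40), tol = 1e-12)$root |> exp()
}

#' Harrell's c-index under right censoring
#'
#' Concordance between a risk score (higher = shorter anticipated survival)
#' and censored survival times, over comparable pairs: pairs in which the
#' smaller observed time is an event. Ties in the score count 0.5. Computed
#' with [survival::concordance()] (with `reverse = TRUE` so that larger
#' scores predict earlier events).
#'
#' @param lp Risk score / linear predictor.
#' @param time Observed times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Harrell's c-index in \[0, 1\].
#' @export
harrell_cindex <- function(lp, time, event) {
  stopifnot(length(lp) == length(time), length(time) == length(event))
  fit <- survival::concordance(survival::Surv(time, event) ~ lp, reverse = TRUE)
  n_pairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (is.na(fit$concordance) || n_pairs == 0)
    stop("no comparable pairs: the c-index is undefined", call. = FALSE)
  unname(fit$concordance)
}

#' Calibration slope for survival models
#'
#' The proportional-hazards analogue of the logistic calibration slope: the
#' coefficient of the estimated linear predictor \eqn{\hat\eta} in a Cox
#' model fitted to validation data, `coxph(Surv(time, event) ~ lp_hat)`.
#' A slope of 1 is ideal; below 1 indicates overfitting.
#'
#' @param lp_hat Estimated linear predictor on validation data.
#' @param time,event Observed survival times and event indicators.
#' @return The calibration slope.
#' @export
survival_calibration_slope <- function(lp_hat, time, event) {
  if (sum(event) == 0)
    stop("no events: the survival calibration slope is undefined", call. = FALSE)
  if (stats::sd(lp_hat) == 0)
    stop("`lp_hat` is constant; the calibration slope is undefined", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ lp_hat)
  unname(stats::coef(fit))
}

#' Cox-Snell R-squared of a survival scenario from a large simulated sample
#'
#' The time-to-event counterpart of [r2cs_from_large_sample()]: simulates a
#' large censored survival dataset, fits the Cox model by partial likelihood
#' and returns \eqn{1 - \exp(-LR/N)}. This is the model-strength input for
#' the calibration sample-size criterion with survival outcomes; it grows
#' with the proportion of observed events, so less censoring implies a
#' smaller recommended sample size.
#'
#' @inheritParams evaluate_performance_survival
#' @param N Number of simulated observations.
#' @param seed Integer seed.
#' @return Estimated \eqn{R^2_{CS}}.
#' @export
r2cs_cox_large_sample <- function(scen, baseline_rate = 0.1,
                                  target_uncensored = 0.5, N = 2e5, seed = 1L) {
  stopifnot(N >= 1e4)
  ct <- calibrate_censor_time(scen$model, baseline_rate, target_uncensored)
  d <- simulate_survival(scen$model, scen$spec, N, baseline_rate, ct, seed = seed)
  fit <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X)
  lr <- 2 * diff(fit$loglik)
  1 - exp(-lr / N)
}

#' Evaluate survival model performance at a development sample size
#'
#' Time-to-event counterpart of [evaluate_performance()]: per replicate, a
#' development sample is drawn from the exponential proportional-hazards
#' mechanism, a Cox model is fitted by partial likelihood, and the survival
#' calibration slope and Harrell's c-index of the fitted linear predictor
#' are measured on a fresh validation sample.
#'
#' @param scen A [survival_scenario()].
#' @param n Development sample size.
#' @param n_sim,n_val Replicates and validation size.
#' @param baseline_rate Constant baseline hazard.
#' @param target_uncensored Proportion of uncensored observations; the
#'   censoring time is calibrated with [calibrate_censor_time()].
#' @param seed Master seed.
#' @return A `surv_perf_distribution` with per-replicate `cs` and `cindex`
#'   and their summaries.
#' @export
evaluate_performance_survival <- function(scen, n, n_sim = 500, n_val = 25000,
                                          baseline_rate = 0.1,
                                          target_uncensored = 0.5, seed = 1L) {
  stopifnot(n >= 2, n_sim >= 2)
  model <- scen$model; spec <- scen$spec
  censor_time <- calibrate_censor_time(model, baseline_rate, target_uncensored)
  dev_seeds <- spawn_seeds(seed, n_sim)
  val_seeds <- spawn_seeds(seed + 1L, n_sim)
  cs <- ci <- numeric(n_sim)
  n_redrawn <- 0L
  for (i in seq_len(n_sim)) {
    set.seed(dev_seeds[i])
    fit <- NULL
    for (attempt in seq_len(100)) {
      d <- simulate_survival(model, spec, n, baseline_rate, censor_time)
      if (sum(d$event) >= 2) {
        f <- tryCatch(survival::coxph(survival::Surv(d$time, d$event) ~ d$X),
                      warning = function(w) NULL, error = function(e) NULL)
        if (!is.null(f) && all(is.finite(stats::coef(f)))) { fit <- f; break }
      }
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(fit))
      stop("Cox development fit failed in 100 consecutive redraws", call. = FALSE)
    bh <- stats::coef(fit)
    set.seed(val_seeds[i])
    v <- simulate_survival(model, spec, n_val, baseline_rate, censor_time)
    lp_hat <- drop(v$X %*% bh)
    cs[i] <- survival_calibration_slope(lp_hat, v$time, v$event)
    ci[i] <- harrell_cindex(lp_hat, v$time, v$event)
  }
  if (n_redrawn > 0.01 * n_sim)
    warning(n_redrawn, " development fits were redrawn (> 1% of n_sim)", call. = FALSE)
  structure(list(n = n, n_sim = n_sim, n_val = n_val, seed = seed,
                 target_uncensored = target_uncensored,
                 censor_time = censor_time,
                 cs = cs, cindex = ci,
                 mean_cs = mean(cs), mcse_cs = mcse(cs),
                 mean_cindex = mean(ci),
                 n_redrawn = n_redrawn),
            class = "surv_perf_distribution")
}

#' @export
print.surv_perf_distribution <- function(x, ...) {
  cat(sprintf("Survival performance at n = %d (%d replicates, %.0f%% uncensored)\n",
              x$n, x$n_sim, 100 * x$target_uncensored))
  cat(sprintf("  mean CS %.4f (MCSE %.4f); mean c-index %.4f\n",
              x$mean_cs, x$mcse_cs, x$mean_cindex))
  invisible(x)
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: n = %d, events = %d (%.3f), censored at %s\n",
              length(x$time), sum(x$event), x$uncensored_prop,
              format(x$censor_time)))
  invisible(x)
}
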