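## Calibration of the normal linear predictor to (prevalence, c-statistic),
## and the Cox-Snell R^2 mappings used by the closed-form criteria.

#' Prevalence induced by a normally distributed linear predictor
#'
#' For a logistic model whose linear predictor \eqn{\eta} is distributed
#' \eqn{N(\mu, \sigma^2)} across the population, the marginal event
#' probability is \eqn{E[\mathrm{expit}(\eta)]}, evaluated here by
#' Gauss-Hermite quadrature.
#'
#' @param mu Mean of the linear predictor.
#' @param sigma Standard deviation of the linear predictor (non-negative).
#' @param n_nodes Number of Gauss-Hermite nodes.
#' @return The induced prevalence, in \[0, 1\].
#' @export
induced_prevalence <- function(mu, sigma, n_nodes = 120L) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(expit(mu))
  gh_expect(expit, mu, sigma, n_nodes)
}

#' c-statistic induced by a normally distributed linear predictor
#'
#' The c-statistic of the true model is the probability that an event patient
#' has a larger linear predictor than a non-event patient,
#' \deqn{c = E[\mathrm{expit}(\eta_1)(1-\mathrm{expit}(\eta_0))
#'        1\{\eta_1>\eta_0\}] / (\phi(1-\phi)),}
#' with \eqn{\eta_0, \eta_1} i.i.d. \eqn{N(\mu, \sigma^2)} and \eqn{\phi} the
#' induced prevalence. The double integral is computed by nested quadrature:
#' Gauss-Hermite in the outer (event) coordinate and Gauss-Legendre for the
#' inner truncated integral. A degenerate linear predictor (`sigma = 0`)
#' yields 0.5: every comparison is a tie.
#'
#' @inheritParams induced_prevalence
#' @param n_inner Number of Gauss-Legendre nodes for the inner integral.
#' @return The induced c-statistic, in \[0.5, 1).
#' @export
induced_cstatistic <- function(mu, sigma, n_nodes = 120L, n_inner = 128L) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(0.5)
  phi <- induced_prevalence(mu, sigma, n_nodes)
  gh <- gh_rule(n_nodes)
  gl <- gl_rule(n_inner)
  lo <- mu - 9 * sigma
  eta1 <- mu + sqrt(2) * sigma * gh$x
  # inner: integral over eta0 < eta1 of (1 - expit(eta0)) dN(eta0; mu, sigma)
  inner <- vapply(eta1, function(e1) {
    u <- (gl$x + 1) / 2 * (e1 - lo) + lo
    sum(gl$w * (1 - expit(u)) * stats::dnorm(u, mu, sigma)) * (e1 - lo) / 2
  }, numeric(1))
  num <- sum(gh$w * expit(eta1) * inner) / sqrt(pi)
  min(max(num / (phi * (1 - phi)), 0.5), 1)
}

#' Calibrate the linear-predictor distribution to (prevalence, c-statistic)
#'
#' Finds the mean and standard deviation \eqn{(\mu, \sigma)} of a normal
#' linear predictor whose induced prevalence and c-statistic equal the
#' anticipated values. The system is solved by nested root-finding: for each
#' candidate \eqn{\sigma}, \eqn{\mu} is solved to match the prevalence (the
#' induced prevalence is strictly increasing in \eqn{\mu}), and \eqn{\sigma}
#' is then solved to match the c-statistic (strictly increasing in
#' \eqn{\sigma}).
#'
#' @param prevalence Target prevalence, in (0, 1).
#' @param c_statistic Target c-statistic, in (0.5, 1).
#' @param tol Tolerance required of both residuals.
#' @return Named vector `c(mu, sigma)`.
#' @examples
#' solve_lp_distribution(0.174, 0.89)
#' @export
solve_lp_distribution <- function(prevalence, c_statistic, tol = 1e-6) {
  check_probability(prevalence, "prevalence")
  stopifnot(c_statistic > 0.5, c_statistic < 1, tol > 0)
  mu_for <- function(sigma) {
    lo <- logit(prevalence) - 3 - 3 * sigma
    hi <- logit(prevalence) + 3 + 3 * sigma
    stats::uniroot(function(m) induced_prevalence(m, sigma) - prevalence,
                   c(lo, hi), tol = min(tol, 1e-9) / 10)$root
  }
  sig_hi <- 10
  while (induced_cstatistic(mu_for(sig_hi), sig_hi) < c_statistic && sig_hi < 60)
    sig_hi <- sig_hi * 2
  sig <- stats::uniroot(function(s) induced_cstatistic(mu_for(s), s) - c_statistic,
                        c(1e-8, sig_hi), tol = 1e-9)$root
  mu <- mu_for(sig)
  res_p <- abs(induced_prevalence(mu, sig) - prevalence)
  res_c <- abs(induced_cstatistic(mu, sig) - c_statistic)
  if (res_p > tol || res_c > tol)
    stop(sprintf("linear-predictor calibration did not converge (residuals: prevalence %.2e, c-statistic %.2e)",
                 res_p, res_c), call. = FALSE)
  c(mu = mu, sigma = sig)
}

#' Cox-Snell R-squared from (prevalence, c-statistic), normal linear predictor
#'
#' Computes the population Cox-Snell \eqn{R^2_{CS}} of a logistic model whose
#' linear predictor is normal with moments calibrated to the anticipated
#' prevalence and c-statistic:
#' \deqn{R^2_{CS} = 1 - \exp\{-2(\bar\ell_{model} - \bar\ell_{null})\},}
#' where \eqn{\bar\ell_{model} = E[\pi\log\pi + (1-\pi)\log(1-\pi)]} with
#' \eqn{\pi = \mathrm{expit}(\eta)} averaged over the linear-predictor
#' distribution, and \eqn{\bar\ell_{null} = \phi\log\phi +
#' (1-\phi)\log(1-\phi)}.
#'
#' This is the exact population value for data generated from a model with an
#' unconditionally normal linear predictor, and hence matches
#' [r2cs_from_large_sample()] on such data. [r2cs_from_cstat()] gives the
#' closely related conversion that instead assumes normality *within* the
#' event and non-event groups.
#'
#' @inheritParams solve_lp_distribution
#' @return \eqn{R^2_{CS}} in \[0, 1).
#' @export
approx_r2cs <- function(prevalence, c_statistic, tol = 1e-6) {
  ms <- solve_lp_distribution(prevalence, c_statistic, tol)
  ll_model <- gh_expect(entropy_from_lp, ms[["mu"]], ms[["sigma"]])
  ll_null <- prevalence * log(prevalence) + (1 - prevalence) * log(1 - prevalence)
  max(0, 1 - exp(-2 * (ll_model - ll_null)))
}

#' Cox-Snell R-squared from a reported c-statistic (binormal conversion)
#'
#' Converts an anticipated c-statistic and prevalence to \eqn{R^2_{CS}}
#' assuming the linear predictor is normal with unit variance within both the
#' event and the non-event group (means separated by
#' \eqn{\sqrt{2}\,\Phi^{-1}(c)}). This is the conversion conventionally used
#' when plugging a published c-statistic into the calibration-slope sample
#' size formula, and is the default \eqn{R^2_{CS}} source of [rvs1_n()].
#'
#' @inheritParams solve_lp_distribution
#' @return \eqn{R^2_{CS}} in \[0, 1).
#' @examples
#' r2cs_from_cstat(0.174, 0.89) # about 0.29
#' @export
r2cs_from_cstat <- function(prevalence, c_statistic) {
  check_probability(prevalence, "prevalence")
  stopifnot(c_statistic > 0.5, c_statistic < 1)
  mu1 <- sqrt(2) * stats::qnorm(c_statistic)
  # implied true model: P(y=1 | lp) = expit(logit(phi) + mu1*lp - mu1^2/2)
  g <- function(lp) entropy_from_lp(logit(prevalence) + mu1 * lp - mu1^2 / 2)
  ll_model <- prevalence * gh_expect(g, mu1, 1) +
    (1 - prevalence) * gh_expect(g, 0, 1)
  ll_null <- prevalence * log(prevalence) + (1 - prevalence) * log(1 - prevalence)
  max(0, 1 - exp(-2 * (ll_model - ll_null)))
}

#' Cox-Snell R-squared estimated from one very large simulated dataset
#'
#' Simulates `N` observations from the calibrated scenario, fits the logistic
#' model by maximum likelihood and returns \eqn{1 - \exp(-LR/N)} where LR is
#' the likelihood-ratio statistic against the intercept-only model. Provided
#' as the simulation route to the "true" \eqn{R^2_{CS}} of a scenario; the
#' analytic [approx_r2cs()] agrees with it up to Monte Carlo error.
#'
#' @param spec A [scenario_spec()].
#' @param N Number of observations (at least 1e5).
#' @param seed Integer seed.
#' @param model Optional pre-calibrated [coefficients_from_lp()] result.
#' @return Estimated \eqn{R^2_{CS}}.
#' @export
r2cs_from_large_sample <- function(spec, N = 1e6, seed = 1L, model = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), N >= 1e5)
  if (is.null(model)) model <- calibrate_scenario(spec)
  d <- simulate_dataset(model, spec, n = N, seed = seed)
  fit <- fit_logistic_mle(d$X, d$y)
  if (!fit$converged) stop("large-sample MLE did not converge", call. = FALSE)
  lr <- fit$deviance_null - fit$deviance_model
  1 - exp(-lr / N)
}

#' Realize regression coefficients for a calibrated scenario
#'
#' Maps the calibrated linear-predictor moments \eqn{(\mu, \sigma)} to a
#' concrete coefficient vector \eqn{\beta = f\gamma} and intercept
#' \eqn{\beta_0} for the scenario's predictor structure, such that
#' \eqn{\mathrm{Var}(\beta^T x) = \sigma^2} and \eqn{E[\beta_0 + \beta^T x] =
#' \mu}. For continuous (zero-mean, unit-variance) predictors with
#' correlation \eqn{R}: \eqn{f = \sigma/\sqrt{\gamma^T R \gamma}} and
#' \eqn{\beta_0 = \mu}. For independent binary predictors the Bernoulli
#' variances replace \eqn{R} and \eqn{\beta_0} absorbs the predictor means.
#'
#' @param spec A [scenario_spec()].
#' @param mu,sigma Linear-predictor mean and standard deviation, typically
#'   from [solve_lp_distribution()].
#' @return An object of class `lp_model`: list with elements `mu`, `sigma`,
#'   `beta0`, `scale_f`, `beta` and `r2cs`.
#' @export
coefficients_from_lp <- function(spec, mu, sigma) {
  stopifnot(inherits(spec, "scenario_spec"), is.finite(mu), sigma >= 0)
  g <- spec$relative_strengths
  if (spec$predictor_kind == "continuous") {
    v <- drop(crossprod(g, spec$correlation %*% g))
    if (v <= 0) stop("relative strengths carry no signal (gamma' R gamma = 0)", call. = FALSE)
    f <- sigma / sqrt(v)
    beta0 <- mu
  } else {
    q <- spec$binary_prevalences
    v <- sum(g^2 * q * (1 - q)) # independent binary predictors
    if (v <= 0) stop("relative strengths carry no signal", call. = FALSE)
    f <- sigma / sqrt(v)
    beta0 <- mu - f * sum(g * q)
  }
  structure(list(mu = mu, sigma = sigma, beta0 = beta0, scale_f = f,
                 beta = f * g,
                 r2cs = NA_real_),
            class = "lp_model")
}

#' Calibrate a scenario end-to-end
#'
#' Convenience wrapper: solves the linear-predictor distribution for the
#' scenario's prevalence and c-statistic, realizes the coefficients, and
#' attaches the analytic Cox-Snell \eqn{R^2_{CS}}.
#'
#' @inheritParams coefficients_from_lp
#' @param tol Calibration tolerance passed to [solve_lp_distribution()].
#' @return An `lp_model`.
#' @export
calibrate_scenario <- function(spec, tol = 1e-6) {
  ms <- solve_lp_distribution(spec$prevalence, spec$c_statistic, tol)
  model <- coefficients_from_lp(spec, ms[["mu"]], ms[["sigma"]])
  model$r2cs <- approx_r2cs(spec$prevalence, spec$c_statistic, tol)
  model
}

#' @export
print.lp_model <- function(x, ...) {
  cat(sprintf("Linear predictor: mu = %.4f, sigma = %.4f (f = %.4f, R2_CS = %.4f)\n",
              x$mu, x$sigma, x$scale_f, x$r2cs))
  invisible(x)
}
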