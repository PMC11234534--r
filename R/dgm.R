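## Data-generating mechanisms for development and validation samples.

#' Simulate a development dataset from a calibrated scenario
#'
#' Continuous predictors are drawn from a multivariate normal distribution
#' with zero mean, unit variances and the scenario's correlation matrix;
#' binary predictors are independent Bernoulli with the scenario's predictor
#' prevalences. Outcomes are Bernoulli with probability
#' \eqn{\mathrm{expit}(\beta_0 + \beta^T x)}.
#'
#' @param model An `lp_model` from [calibrate_scenario()] /
#'   [coefficients_from_lp()].
#' @param spec The matching [scenario_spec()].
#' @param n Number of observations.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage substreams themselves).
#' @return A `simulated_dataset`: list with the predictor matrix `X`, binary
#'   outcome `y`, true event probabilities `pi_true` and true linear
#'   predictor `lp_true`.
#' @export
simulate_dataset <- function(model, spec, n, seed = NULL) {
  stopifnot(inherits(model, "lp_model"), inherits(spec, "scenario_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$n_params
  if (spec$predictor_kind == "continuous") {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (!identical(spec$correlation, diag(p)) &&
        max(abs(spec$correlation - diag(p))) > 0)
      X <- X %*% chol(spec$correlation)
  } else {
    q <- spec$binary_prevalences
    X <- matrix(stats::rbinom(n * p, 1L, rep(q, each = n)), n, p)
  }
  lp <- drop(model$beta0 + X %*% model$beta)
  pi_true <- expit(lp)
  y <- stats::rbinom(n, 1L, pi_true)
  structure(list(X = X, y = y, pi_true = pi_true, lp_true = lp),
            class = "simulated_dataset")
}

#' Simulate a large validation dataset
#'
#' Same data-generating mechanism as [simulate_dataset()]; validation sets
#' are large (default 25,000; 100,000 in study-replication mode) so that
#' performance metrics of a fitted model are measured with little noise.
#'
#' @inheritParams simulate_dataset
#' @param n_val Validation sample size.
#' @export
simulate_validation <- function(model, spec, n_val = 25000, seed = NULL) {
  simulate_dataset(model, spec, n = n_val, seed = seed)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: n = %d, p = %d, events = %d (%.3f)\n",
              nrow(x$X), ncol(x$X), sum(x$y), mean(x$y)))
  invisible(x)
}
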