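## Model fitting and predictive-performance measures.

#' Fit a logistic regression model by maximum likelihood
#'
#' Thin wrapper around the iteratively reweighted least squares fit used by
#' `stats::glm`, returning the quantities the simulation engine needs:
#' coefficients (intercept first), null and model deviances, a convergence
#' flag, and a quasi-separation flag (fitted probabilities numerically 0/1 or
#' exploding coefficients).
#'
#' @param X Predictor matrix (without intercept column).
#' @param y Binary outcome vector; both classes must be present.
#' @return A `logistic_fit`: list with `coef`, `converged`,
#'   `separation_flag`, `deviance_null`, `deviance_model`.
#' @export
fit_logistic_mle <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("outcome has a single class; the MLE does not exist", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  mu <- fit$fitted.values
  sep <- any(mu < 1e-10 | mu > 1 - 1e-10) || max(abs(fit$coefficients)) > 25
  phat <- mean(y)
  dev_null <- -2 * (sum(y) * log(phat) + sum(1 - y) * log(1 - phat))
  structure(list(coef = unname(fit$coefficients),
                 converged = isTRUE(fit$converged),
                 separation_flag = sep,
                 deviance_null = dev_null,
                 deviance_model = fit$deviance),
            class = "logistic_fit")
}

# Two-parameter logistic Newton fit of y on eta (intercept + slope).
# Falls back to glm.fit when Newton does not converge.
fit_slope <- function(eta, y) {
  b0 <- 0; b1 <- 1
  n <- length(y)
  for (it in seq_len(30)) {
    lp <- b0 + b1 * eta
    p <- expit(lp)
    w <- p * (1 - p)
    r <- y - p
    g0 <- sum(r); g1 <- sum(r * eta)
    h00 <- sum(w); h01 <- sum(w * eta); h11 <- sum(w * eta * eta)
    det <- h00 * h11 - h01 * h01
    if (!is.finite(det) || det <= 1e-12) break
    d0 <- (h11 * g0 - h01 * g1) / det
    d1 <- (-h01 * g0 + h00 * g1) / det
    # dampen unusually large steps for stability far from the optimum
    step <- max(abs(d0), abs(d1))
    if (step > 5) { d0 <- d0 * 5 / step; d1 <- d1 * 5 / step }
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < 1e-10) return(c(b0, b1))
  }
  fit <- suppressWarnings(stats::glm.fit(cbind(1, eta), y, family = stats::binomial()))
  unname(fit$coefficients)
}

#' Calibration slope
#'
#' The slope \eqn{\alpha_1} from the logistic calibration model
#' \eqn{\mathrm{logit}\,P(y_i = 1) = \alpha_0 + \alpha_1 \hat\eta_i} fitted
#' to validation data, where \eqn{\hat\eta} is the linear predictor of the
#' model under evaluation. A slope of 1 is ideal; values below 1 indicate
#' overfitting.
#'
#' @param lp_hat Estimated linear predictor on the validation data (must have
#'   non-zero variance).
#' @param y Observed binary outcomes.
#' @return The calibration slope.
#' @export
calibration_slope <- function(lp_hat, y) {
  stopifnot(length(lp_hat) == length(y), all(y %in% c(0, 1)))
  if (stats::sd(lp_hat) == 0)
    stop("`lp_hat` is constant; the calibration slope is undefined", call. = FALSE)
  fit_slope(lp_hat, y)[2]
}

#' c-statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event patient receives a higher
#' predicted risk than a randomly chosen non-event patient, with ties
#' counted 0.5. Computed in O(n log n) from midranks; exactly equal to the
#' all-pairs estimator
#' \eqn{\sum_{ij} I(y_i=1, y_j=0)\{I(\hat\pi_i > \hat\pi_j) +
#'   0.5 I(\hat\pi_i = \hat\pi_j)\} / \sum_{ij} I(y_i=1, y_j=0)}.
#'
#' @param pi_hat Predicted risks (any strictly increasing transform gives the
#'   same value).
#' @param y Observed binary outcomes; both classes must be present.
#' @return The c-statistic, in \[0, 1\].
#' @export
c_statistic <- function(pi_hat, y) {
  stopifnot(length(pi_hat) == length(y), all(y %in% c(0, 1)))
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present to compute the c-statistic", call. = FALSE)
  r <- rank(pi_hat) # midranks score ties at 0.5
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean absolute prediction error (MAPE)
#'
#' Mean absolute difference between estimated and true event probabilities,
#' \eqn{n^{-1}\sum_i |\hat\pi_i - \pi_i|}. Only computable when the true
#' probabilities are known, i.e. in simulation.
#'
#' @param pi_hat Estimated probabilities.
#' @param pi_true True probabilities (same length).
#' @return Non-negative mean absolute error.
#' @export
mape <- function(pi_hat, pi_true) {
  if (length(pi_hat) != length(pi_true))
    stop("`pi_hat` and `pi_true` must have the same length", call. = FALSE)
  mean(abs(pi_hat - pi_true))
}

#' Root mean square distance of the calibration slope from 1
#'
#' \eqn{\sqrt{\mathrm{mean}((CS_i - 1)^2)}} across replicates; combines the
#' bias and the variability of the calibration slope into one stability
#' measure.
#'
#' @param cs_values Vector of per-replicate calibration slopes.
#' @return Non-negative RMSD.
#' @export
rmsd_cs <- function(cs_values) {
  stopifnot(length(cs_values) >= 1)
  sqrt(mean((cs_values - 1)^2))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic MLE: %d parameters, LR = %.2f, converged: %s%s\n",
              length(x$coef) - 1, x$deviance_null - x$deviance_model,
              x$converged, if (x$separation_flag) " (separation suspected)" else ""))
  invisible(x)
}
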