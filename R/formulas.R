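## Closed-form sample-size criteria (calibration / MAPE) and shrinkage.

new_formula_result <- function(criterion, n_raw, rounding, p, prevalence, inputs) {
  structure(list(criterion = criterion,
                 n_raw = n_raw,
                 n = round_n(n_raw, rounding),
                 rounding = rounding,
                 epv = if (is.null(prevalence)) NA_real_ else epv(n_raw, prevalence, p),
                 inputs = inputs),
            class = "formula_result")
}

#' Sample size to control overfitting (target expected calibration slope)
#'
#' The calibration criterion: the development sample size needed so that a
#' logistic model with `p` predictor parameters, fitted by maximum
#' likelihood, has expected calibration slope (equivalently, required
#' shrinkage factor) equal to `S_target`:
#' \deqn{n = \frac{p}{(S-1)\log(1 - R^2_{CS}/S)}.}
#'
#' The model strength enters through the Cox-Snell \eqn{R^2_{CS}}, supplied
#' either directly via `r2cs`, or derived from an anticipated prevalence and
#' c-statistic. In the latter case the default conversion is the binormal
#' c-statistic mapping [r2cs_from_cstat()] (`r2_method = "cstat"`); the
#' unconditional normal-linear-predictor value [approx_r2cs()]
#' (`"normal_lp"`) and the large-sample simulation estimate
#' (`"large_sample"`) are available for fidelity checks.
#'
#' Note that the expected MAPE criterion [rvs2_n()] and this criterion answer
#' different questions; practitioners run both and take the maximum.
#'
#' @param p Number of predictor parameters (excluding intercept).
#' @param S_target Target expected calibration slope, in (0, 1); values below
#'   0.9 are not recommended.
#' @param r2cs Anticipated Cox-Snell R-squared, in (0, `S_target`). If
#'   missing, derived from `prevalence` and `c_statistic`.
#' @param prevalence,c_statistic Anticipated outcome prevalence and
#'   c-statistic (used when `r2cs` is missing).
#' @param r2_method How to derive \eqn{R^2_{CS}} from (prevalence,
#'   c-statistic): `"cstat"`, `"normal_lp"` or `"large_sample"`.
#' @param rounding `"up10"` (default, user-facing recommendation) or
#'   `"nearest10"` (grid-table convention).
#' @param N,seed Large-sample size and seed, for `r2_method = "large_sample"`.
#' @return A `formula_result`: list with `n_raw`, `n` (rounded), `epv`
#'   (computed from the unrounded size) and the echoed inputs.
#' @examples
#' rvs1_n(p = 24, S_target = 0.9, prevalence = 0.174, c_statistic = 0.89)
#' @export
rvs1_n <- function(p, S_target = 0.9, r2cs = NULL,
                   prevalence = NULL, c_statistic = NULL,
                   r2_method = c("cstat", "normal_lp", "large_sample"),
                   rounding = c("up10", "nearest10"),
                   N = 1e6, seed = 1L) {
  rounding <- match.arg(rounding)
  r2_method <- match.arg(r2_method)
  stopifnot(p >= 1, S_target > 0, S_target < 1)
  if (is.null(r2cs)) {
    if (is.null(prevalence) || is.null(c_statistic))
      stop("supply either `r2cs` or both `prevalence` and `c_statistic`", call. = FALSE)
    r2cs <- switch(r2_method,
      cstat = r2cs_from_cstat(prevalence, c_statistic),
      normal_lp = approx_r2cs(prevalence, c_statistic),
      large_sample = r2cs_from_large_sample(
        scenario_spec(prevalence, c_statistic, n_params = p), N = N, seed = seed))
  }
  if (r2cs <= 0 || r2cs >= S_target)
    stop(sprintf("R2_CS (%.4f) must lie in (0, S_target = %.3f): the shrinkage target is otherwise unattainable",
                 r2cs, S_target), call. = FALSE)
  n_raw <- p / ((S_target - 1) * log(1 - r2cs / S_target))
  new_formula_result("rvs1_calibration", n_raw, rounding, p, prevalence,
                     list(p = p, S_target = S_target, r2cs = r2cs,
                          prevalence = prevalence, c_statistic = c_statistic,
                          r2_method = r2_method))
}

#' Sample size for accurate individual risks (target expected MAPE)
#'
#' The MAPE criterion: development sample size needed so that the expected
#' mean absolute prediction error of a `p`-parameter logistic model equals
#' `m_target`, given anticipated outcome prevalence \eqn{\phi}:
#' \deqn{n = \exp\left(\frac{-0.508 + 0.259\log\phi + 0.504\log p -
#'   \log m}{0.544}\right).}
#' Model strength does not enter this criterion.
#'
#' @param p Number of predictor parameters (excluding intercept).
#' @param prevalence Anticipated outcome prevalence, in (0, 1).
#' @param m_target Target expected MAPE (> 0); values above 0.05 are not
#'   recommended, and `prevalence/10` is a common choice.
#' @inheritParams rvs1_n
#' @return A `formula_result` (see [rvs1_n()]).
#' @examples
#' rvs2_n(p = 24, prevalence = 0.174, m_target = 0.05) # n = 800
#' @export
rvs2_n <- function(p, prevalence, m_target,
                   rounding = c("nearest10", "up10")) {
  rounding <- match.arg(rounding)
  check_probability(prevalence, "prevalence")
  stopifnot(p >= 1, m_target > 0)
  n_raw <- exp((-0.508 + 0.259 * log(prevalence) + 0.504 * log(p) - log(m_target)) / 0.544)
  new_formula_result("rvs2_mape", n_raw, rounding, p, prevalence,
                     list(p = p, prevalence = prevalence, m_target = m_target))
}

#' Heuristic shrinkage factor
#'
#' The heuristic (deviance-based) estimate of the shrinkage needed after
#' maximum-likelihood fitting: \eqn{S = (\Delta\chi^2 - p)/\Delta\chi^2},
#' where \eqn{\Delta\chi^2} is the model's likelihood-ratio statistic and `p`
#' the number of predictor parameters. Valid for modest model strength; for
#' strong models it understates the shrinkage actually required.
#'
#' @param delta_chi2 Likelihood-ratio (deviance) statistic, > 0.
#' @param p Number of predictor parameters.
#' @return The shrinkage factor (at most 1; can be negative for
#'   uninformative models).
#' @export
heuristic_shrinkage <- function(delta_chi2, p) {
  stopifnot(delta_chi2 > 0, p >= 1)
  (delta_chi2 - p) / delta_chi2
}

#' Events per variable
#'
#' @param n Sample size.
#' @param prevalence Outcome prevalence.
#' @param p Number of predictor parameters.
#' @return `n * prevalence / p`.
#' @export
epv <- function(n, prevalence, p) {
  stopifnot(n > 0, p > 0)
  check_probability(prevalence, "prevalence")
  n * prevalence / p
}

#' @export
print.formula_result <- function(x, ...) {
  lab <- switch(x$criterion,
                rvs1_calibration = "calibration (expected CS)",
                rvs2_mape = "MAPE")
  cat(sprintf("Sample size [%s criterion]: n = %d (raw %.1f, %s)", lab,
              x$n, x$n_raw, x$rounding))
  if (!is.na(x$epv)) cat(sprintf(", EPV = %.1f", x$epv))
  cat("\n")
  invisible(x)
}
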