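#' Specify an anticipated model-development scenario
#'
#' A scenario collects the design quantities that a sample-size calculation
#' for a risk prediction model is based on: the anticipated outcome prevalence
#' \eqn{\phi}, the anticipated c-statistic \eqn{c} of the (true) model, the
#' number of predictor parameters \eqn{p}, and the structure of the predictors
#' (relative strengths, correlation, continuous or binary).
#'
#' The relative strengths \eqn{\gamma} fix the *shape* of the coefficient
#' vector only; the overall signal is rescaled (and the intercept chosen) so
#' that the induced prevalence and c-statistic match \eqn{\phi} and \eqn{c}
#' (see [calibrate_scenario()]). By default all predictors carry equal weight.
#'
#' @param prevalence Anticipated outcome prevalence, in (0, 1).
#' @param c_statistic Anticipated c-statistic of the true model, in (0.5, 1).
#' @param n_params Number of predictor parameters `p` (excluding intercept).
#' @param relative_strengths Non-negative vector of length `n_params` with at
#'   least one positive entry; default equal strengths.
#' @param correlation `p` x `p` predictor correlation matrix (continuous
#'   predictors); default identity. See [make_correlation_matrix()] for the
#'   block-exchangeable shorthand.
#' @param predictor_kind `"continuous"` (multivariate normal, zero mean, unit
#'   variance) or `"binary"` (independent Bernoulli predictors).
#' @param binary_prevalences For binary predictors, vector of predictor
#'   prevalences in (0, 1); defaults to an even grid on [0.2, 0.7].
#' @return An object of class `scenario_spec`.
#' @seealso [main_study_spec()] for the 5-true/7-noise reference scenario.
#' @examples
#' scenario_spec(prevalence = 0.174, c_statistic = 0.89, n_params = 24)
#' @export
scenario_spec <- function(prevalence, c_statistic, n_params,
                          relative_strengths = NULL,
                          correlation = NULL,
                          predictor_kind = c("continuous", "binary"),
                          binary_prevalences = NULL) {
  predictor_kind <- match.arg(predictor_kind)
  check_probability(prevalence, "prevalence")
  if (!is.numeric(c_statistic) || length(c_statistic) != 1 ||
      c_statistic <= 0.5 || c_statistic >= 1)
    stop("`c_statistic` must lie in (0.5, 1)", call. = FALSE)
  stopifnot(n_params >= 1, n_params == as.integer(n_params))
  p <- as.integer(n_params)
  if (is.null(relative_strengths)) relative_strengths <- rep(1, p)
  if (length(relative_strengths) != p || any(relative_strengths < 0) ||
      !any(relative_strengths > 0))
    stop("`relative_strengths` must be length n_params, non-negative, with at least one positive entry",
         call. = FALSE)
  if (is.null(correlation)) correlation <- diag(p)
  validate_correlation(correlation, p)
  if (predictor_kind == "binary") {
    if (is.null(binary_prevalences))
      binary_prevalences <- seq(0.2, 0.7, length.out = p)
    if (length(binary_prevalences) != p ||
        any(binary_prevalences <= 0) || any(binary_prevalences >= 1))
      stop("`binary_prevalences` must be length n_params, all in (0, 1)", call. = FALSE)
  } else {
    binary_prevalences <- NULL
  }
  structure(
    list(prevalence = prevalence, c_statistic = c_statistic,
         n_params = p, relative_strengths = as.numeric(relative_strengths),
         correlation = unname(as.matrix(correlation)),
         predictor_kind = predictor_kind,
         binary_prevalences = binary_prevalences),
    class = "scenario_spec")
}

validate_correlation <- function(R, p) {
  R <- as.matrix(R)
  if (nrow(R) != p || ncol(R) != p)
    stop("correlation matrix must be ", p, "x", p, call. = FALSE)
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
    stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

#' Block-exchangeable predictor correlation matrix
#'
#' Builds the correlation matrix of a predictor set consisting of `n_true`
#' true predictors and `n_noise` noise predictors, with exchangeable
#' correlations within and between the two blocks.
#'
#' @param n_true,n_noise Block sizes (non-negative integers).
#' @param r_tt Correlation between pairs of true predictors.
#' @param r_nn Correlation between pairs of noise predictors.
#' @param r_tn Correlation between a true and a noise predictor (default 0).
#' @return A `(n_true + n_noise)` square correlation matrix.
#' @examples
#' R <- make_correlation_matrix(5, 7, 0.1, 0.05) # the 12-predictor reference set
#' @export
make_correlation_matrix <- function(n_true, n_noise, r_tt, r_nn, r_tn = 0) {
  stopifnot(n_true >= 0, n_noise >= 0, n_true + n_noise >= 1)
  p <- n_true + n_noise
  R <- matrix(0, p, p)
  if (n_true > 0) R[seq_len(n_true), seq_len(n_true)] <- r_tt
  if (n_noise > 0) R[n_true + seq_len(n_noise), n_true + seq_len(n_noise)] <- r_nn
  if (n_true > 0 && n_noise > 0) {
    R[seq_len(n_true), n_true + seq_len(n_noise)] <- r_tn
    R[n_true + seq_len(n_noise), seq_len(n_true)] <- r_tn
  }
  diag(R) <- 1
  validate_correlation(R, p)
  R
}

#' Reference 12-predictor scenario (5 true + 7 noise predictors)
#'
#' The standard evaluation scenario: 12 multivariate-normal predictors of
#' which 5 are true predictors with relative strengths (0.4, 0.2, 0.2, 0.1,
#' 0.1) and 7 are noise, pairwise correlations 0.1 among true predictors,
#' 0.05 among noise predictors and 0 between the blocks.
#'
#' @inheritParams scenario_spec
#' @return A `scenario_spec`.
#' @export
main_study_spec <- function(prevalence, c_statistic) {
  scenario_spec(prevalence, c_statistic, n_params = 12L,
                relative_strengths = c(0.4, 0.2, 0.2, 0.1, 0.1, rep(0, 7)),
                correlation = make_correlation_matrix(5, 7, 0.1, 0.05, 0))
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario: prevalence", x$prevalence, "| c-statistic", x$c_statistic,
      "|", x$n_params, x$predictor_kind, "predictors\n")
  invisible(x)
}

#' Serialize / deserialize a scenario to JSON
#'
#' The correlation matrix may be given explicitly or via the shorthand
#' `list(n_true=, n_noise=, r_true_true=, r_noise_noise=, r_true_noise=)`.
#'
#' @param spec A `scenario_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `scenario_to_json()`: JSON string (invisibly, if written to file);
#'   `scenario_from_json()`: a `scenario_spec`.
#' @export
scenario_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  js <- jsonlite::toJSON(unclass(spec), digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname scenario_to_json
#' @param json JSON string or file path to parse.
#' @export
scenario_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  corr <- x$correlation
  if (is.list(corr) && !is.null(corr$n_true)) {
    corr <- make_correlation_matrix(corr$n_true, corr$n_noise,
                                    corr$r_true_true, corr$r_noise_noise,
                                    if (is.null(corr$r_true_noise)) 0 else corr$r_true_noise)
  } else if (!is.null(corr)) {
    corr <- matrix(unlist(corr), nrow = x$n_params)
  }
  scenario_spec(prevalence = x$prevalence, c_statistic = x$c_statistic,
                n_params = x$n_params,
                relative_strengths = x$relative_strengths,
                correlation = corr,
                predictor_kind = if (is.null(x$predictor_kind)) "continuous" else x$predictor_kind,
                binary_prevalences = x$binary_prevalences)
}
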