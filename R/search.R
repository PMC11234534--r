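## Simulation-based sample-size search (bisection on the mean CS or MAPE).

# Shared search driver. metric_fun(perf) extracts the mean metric; increasing
# says whether the metric grows with n (CS: TRUE, MAPE: FALSE).
search_n <- function(spec, target, metric, n_sim, n_val, seed, tol,
                     n_start, model, grid = 10L, n_min = NULL, max_expand = 12L) {
  if (is.null(model)) model <- calibrate_scenario(spec)
  increasing <- metric == "cs"
  if (is.null(n_min)) n_min <- max(50L, as.integer(2 * spec$n_params + 10))
  g <- function(n) max(n_min, as.integer(round(n / grid) * grid))
  cache <- new.env(parent = emptyenv())
  trace <- list()
  ev <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perf <- evaluate_performance(spec, n, n_sim = n_sim, n_val = n_val,
                                 seed = seed, model = model)
    val <- if (metric == "cs") perf$mean_cs else perf$mean_mape
    se <- if (metric == "cs") perf$mcse_cs else perf$mcse_mape
    cache[[key]] <- list(n = n, value = val, mcse = se)
    trace[[length(trace) + 1L]] <<- cache[[key]]
    cache[[key]]
  }
  # signed distance above target in the direction of increasing n
  above <- function(e) if (increasing) e$value >= target else e$value <= target
  lo <- g(n_start / 2); hi <- g(n_start * 4)
  if (hi <= lo) hi <- lo + grid
  e_lo <- ev(lo); e_hi <- ev(hi)
  expand <- 0L
  while (above(e_lo) && lo > n_min && expand < max_expand) {
    hi <- lo; e_hi <- e_lo
    lo <- g(lo / 2)
    e_lo <- ev(lo); expand <- expand + 1L
  }
  while (!above(e_hi) && expand < max_expand) {
    lo <- hi; e_lo <- e_hi
    hi <- g(hi * 2)
    e_hi <- ev(hi); expand <- expand + 1L
  }
  message_note <- NULL
  if (above(e_lo) && lo <= n_min) {
    message_note <- sprintf(
      "target already met at the minimum sample size considered (n = %d); returning the lower bound", n_min)
    return(finish_search(metric, target, lo, e_lo, trace, seed, spec, message_note))
  }
  if (!above(e_hi))
    stop("could not bracket the target after ", max_expand,
         " expansions; last mean ", metric, " = ", format(e_hi$value),
         " at n = ", e_hi$n, call. = FALSE)
  while (hi - lo > grid) {
    mid <- g((lo + hi) / 2)
    if (mid <= lo || mid >= hi) break
    e_mid <- ev(mid)
    if (above(e_mid)) { hi <- mid; e_hi <- e_mid } else { lo <- mid; e_lo <- e_mid }
  }
  chosen <- e_hi
  if (abs(chosen$value - target) > tol && e_hi$value != e_lo$value) {
    # refine by linear interpolation across the final bracket, then confirm
    n_star <- e_lo$n + (target - e_lo$value) * (e_hi$n - e_lo$n) / (e_hi$value - e_lo$value)
    n_star <- max(n_min, as.integer(ceiling(n_star / grid) * grid))
    chosen <- ev(n_star)
  }
  finish_search(metric, target, chosen$n, chosen, trace, seed, spec, message_note)
}

finish_search <- function(metric, target, n_found, e, trace, seed, spec, note) {
  tr <- do.call(rbind, lapply(trace, function(t)
    data.frame(n = t$n, metric = t$value, mcse = t$mcse)))
  tr <- tr[order(tr$n), , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(
    criterion = if (metric == "cs") "expected_cs" else "expected_mape",
    target = target, n_found = as.integer(n_found),
    achieved = e$value, achieved_mcse = e$mcse,
    evaluations = tr, seed = seed,
    epv = epv(n_found, spec$prevalence, spec$n_params),
    note = note),
    class = "sample_size_result")
}

#' Sample size achieving a target expected calibration slope, by simulation
#'
#' Finds the development sample size at which the mean validation calibration
#' slope of maximum-likelihood logistic models equals `S_target`. Starting
#' from a bracket around the closed-form calibration criterion [rvs1_n()],
#' the mean CS (estimated by [evaluate_performance()] with common random
#' numbers across candidate sizes) is bisected on a 10-participant grid
#' until the bracket collapses; if the bracket endpoint still misses the
#' target by more than `tol_cs`, one linear-interpolation refinement is
#' evaluated. The returned size is the smallest grid point whose mean CS
#' reaches the target.
#'
#' @param spec A [scenario_spec()].
#' @param S_target Target expected calibration slope, in (0, 1); values
#'   outside \[0.85, 0.95\] trigger a warning.
#' @param n_sim,n_val Replicates and validation size per evaluation (defaults
#'   1000 and 25,000, which keep the MCSE of the mean CS near 0.0025 at the
#'   solution).
#' @param seed Master seed (shared across candidate sizes: common random
#'   numbers).
#' @param tol_cs Stopping tolerance on |mean CS - target|.
#' @param model Optional pre-calibrated `lp_model`.
#' @return A `sample_size_result`: criterion, target, `n_found` (multiple of
#'   10), achieved metric with its MCSE, the full evaluation trace, and the
#'   implied events per variable.
#' @examples
#' \donttest{
#' spec <- scenario_spec(0.174, 0.89, 24)
#' find_n_for_cs(spec, S_target = 0.9, n_sim = 300, n_val = 10000, seed = 1)
#' }
#' @export
find_n_for_cs <- function(spec, S_target = 0.9, n_sim = 1000, n_val = 25000,
                          seed = 1L, tol_cs = 0.005, model = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), S_target > 0, S_target < 1)
  if (S_target < 0.7) stop("target expected CS below 0.7 is not supported", call. = FALSE)
  if (S_target < 0.85 || S_target > 0.95)
    warning("target expected CS outside [0.85, 0.95]; the usual recommendation is 0.9 or higher",
            call. = FALSE)
  if (is.null(model)) model <- calibrate_scenario(spec)
  r2 <- model$r2cs
  n_start <- rvs1_n(spec$n_params, S_target, r2cs = min(r2, S_target - 0.01))$n_raw
  search_n(spec, S_target, metric = "cs", n_sim = n_sim, n_val = n_val,
           seed = seed, tol = tol_cs, n_start = n_start, model = model)
}

#' Sample size achieving a target expected MAPE, by simulation
#'
#' As [find_n_for_cs()], but bisecting the mean MAPE (which decreases with
#' `n`), with the starting bracket taken around the closed-form MAPE
#' criterion [rvs2_n()]. A common choice of target is `prevalence/10`.
#'
#' @inheritParams find_n_for_cs
#' @param m_target Target expected MAPE (> 0).
#' @param tol_m Stopping tolerance on |mean MAPE - target| (default
#'   `0.002 * m_target`).
#' @return A `sample_size_result` (see [find_n_for_cs()]).
#' @export
find_n_for_mape <- function(spec, m_target, n_sim = 1000, n_val = 25000,
                            seed = 1L, tol_m = 0.002 * m_target, model = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), m_target > 0)
  n_start <- rvs2_n(spec$n_params, spec$prevalence, m_target)$n_raw
  res <- search_n(spec, m_target, metric = "mape", n_sim = n_sim, n_val = n_val,
                  seed = seed, tol = tol_m, n_start = n_start, model = model)
  res
}

#' @export
print.sample_size_result <- function(x, ...) {
  lab <- if (x$criterion == "expected_cs") "expected calibration slope" else "expected MAPE"
  cat(sprintf("Simulation-based sample size [%s = %g]\n", lab, x$target))
  cat(sprintf("  n = %d (EPV %.1f); achieved %.4f (MCSE %.4f) in %d evaluations\n",
              x$n_found, x$epv, x$achieved, x$achieved_mcse, nrow(x$evaluations)))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
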