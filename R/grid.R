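## Scenario-grid studies and plain-text reporting.

#' Run a grid of sample-size scenarios
#'
#' Evaluates the closed-form criteria over a grid of (prevalence,
#' c-statistic) scenarios and, optionally, the simulation-based search
#' and/or the Monte Carlo performance at the formula size. One row per
#' scenario; failures in individual rows are recorded in the `error` column
#' and do not stop the run.
#'
#' @param prevalences,c_statistics Vectors defining the grid (crossed).
#' @param n_params Number of predictor parameters.
#' @param S_target Target expected calibration slope for the calibration
#'   criterion.
#' @param m_target Target expected MAPE; default `prevalence/10` per row.
#' @param n_source `"formula"` for closed-form sizes only, or
#'   `"simulation"` to also run the bisection search for both criteria.
#' @param evaluate If `TRUE`, also evaluate mean CS / MAPE (and stability
#'   summaries) at the calibration-formula size.
#' @param scenario_fun Function `(prevalence, c_statistic)` returning the
#'   `scenario_spec` per cell; defaults to [main_study_spec()] when
#'   `n_params` is 12, else equal-strength independent predictors.
#' @param n_sim,n_val,seed Simulation controls (used when searching or
#'   evaluating).
#' @return A data.frame with the formula sizes/EPVs and, when requested,
#'   simulation results.
#' @export
run_grid <- function(prevalences, c_statistics, n_params = 12L,
                     S_target = 0.9, m_target = NULL,
                     n_source = c("formula", "simulation"),
                     evaluate = FALSE, scenario_fun = NULL,
                     n_sim = 500, n_val = 25000, seed = 1L) {
  n_source <- match.arg(n_source)
  if (is.null(scenario_fun))
    scenario_fun <- if (n_params == 12L) main_study_spec else
      function(phi, c) scenario_spec(phi, c, n_params)
  cells <- expand.grid(prevalence = prevalences, c_statistic = c_statistics,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    phi <- cells$prevalence[i]; cst <- cells$c_statistic[i]
    m <- if (is.null(m_target)) phi / 10 else m_target
    out <- data.frame(prevalence = phi, c_statistic = cst, n_params = n_params,
                      n_rvs1 = NA_integer_, epv_rvs1 = NA_real_,
                      n_rvs2 = NA_integer_, epv_rvs2 = NA_real_,
                      n_sim_cs = NA_integer_, epv_sim_cs = NA_real_,
                      n_sim_mape = NA_integer_, epv_sim_mape = NA_real_,
                      mean_cs = NA_real_, mcse_cs = NA_real_,
                      rmsd_cs = NA_real_, p_cs_below_08 = NA_real_,
                      p_cstat_within_002 = NA_real_,
                      mean_mape = NA_real_, mcse_mape = NA_real_,
                      error = NA_character_)
    tryCatch({
      spec <- scenario_fun(phi, cst)
      model <- calibrate_scenario(spec)
      f1 <- rvs1_n(n_params, S_target, r2cs = model$r2cs, rounding = "nearest10")
      f2 <- rvs2_n(n_params, phi, m)
      out$n_rvs1 <- f1$n; out$epv_rvs1 <- f1$epv
      out$n_rvs2 <- f2$n; out$epv_rvs2 <- f2$epv
      if (n_source == "simulation") {
        s1 <- find_n_for_cs(spec, S_target, n_sim = n_sim, n_val = n_val,
                            seed = seed, model = model)
        s2 <- find_n_for_mape(spec, m, n_sim = n_sim, n_val = n_val,
                              seed = seed, model = model)
        out$n_sim_cs <- s1$n_found; out$epv_sim_cs <- s1$epv
        out$n_sim_mape <- s2$n_found; out$epv_sim_mape <- s2$epv
      }
      if (evaluate) {
        perf <- evaluate_performance(spec, f1$n, n_sim = n_sim, n_val = n_val,
                                     seed = seed, model = model)
        out$mean_cs <- perf$mean_cs; out$mcse_cs <- perf$mcse_cs
        out$rmsd_cs <- perf$rmsd_cs; out$p_cs_below_08 <- perf$p_cs_below_08
        out$p_cstat_within_002 <- perf$p_cstat_within_002
        out$mean_mape <- perf$mean_mape; out$mcse_mape <- perf$mcse_mape
      }
      out
    }, error = function(e) { out$error <- conditionMessage(e); out })
  })
  do.call(rbind, rows)
}

#' Plain-text summary of simulation results
#'
#' Produces a human-readable summary (a character vector of lines, also
#' printed) for the objects this package computes: a
#' [evaluate_performance()] distribution, a [find_n_for_cs()] /
#' [find_n_for_mape()] search result, or a [run_grid()] table.
#'
#' @param results One of the result objects above.
#' @return The summary lines, invisibly.
#' @export
report <- function(results) {
  lines <- if (inherits(results, "perf_distribution")) {
    c(sprintf("Development sample size n = %d (%d replicates, n_val = %d)",
              results$n, results$n_sim, results$n_val),
      sprintf("Expected calibration slope: %.3f (MCSE %.4f)",
              results$mean_cs, results$mcse_cs),
      sprintf("Stability: SD(CS) = %.3f, RMSD(CS from 1) = %.3f, P(CS<0.8) = %.3f, P(CS<0.9) = %.3f",
              results$sd_cs, results$rmsd_cs, results$p_cs_below_08, results$p_cs_below_09),
      sprintf("Expected MAPE: %.4f (MCSE %.5f)", results$mean_mape, results$mcse_mape),
      sprintf("Discrimination: mean c-statistic %.3f vs true %.3f; P(within 0.02) = %.3f",
              results$mean_cstat, results$true_cstat, results$p_cstat_within_002))
  } else if (inherits(results, "sample_size_result")) {
    c(sprintf("Criterion: %s, target %g", results$criterion, results$target),
      sprintf("Required sample size: %d (EPV %.1f)", results$n_found, results$epv),
      sprintf("Achieved %.4f with MCSE %.4f after %d evaluations",
              results$achieved, results$achieved_mcse, nrow(results$evaluations)))
  } else if (is.data.frame(results)) {
    if (nrow(results) == 0) stop("empty results table: nothing to report", call. = FALSE)
    c("Scenario grid:", utils::capture.output(print(results, row.names = FALSE)))
  } else stop("no report method for this object", call. = FALSE)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write / read results as JSON
#'
#' Result objects (performance distributions, search results, grid tables)
#' round-trip through JSON for use by scripts and the command-line
#' interface. Class information is preserved so that re-loaded results
#' reproduce the same [report()] output.
#'
#' @param x Result object.
#' @param path Output file path.
#' @return `write_results()`: `path`, invisibly. `read_results()`: the
#'   restored object.
#' @export
write_results <- function(x, path) {
  cls <- class(x)[1]
  payload <- list(class = cls,
                  data = if (is.data.frame(x)) x else unclass(
                    x[setdiff(names(x), c("spec", "model"))]))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  payload <- jsonlite::fromJSON(path)
  x <- payload$data
  if (payload$class %in% c("perf_distribution", "sample_size_result",
                           "surv_perf_distribution")) {
    if (!is.null(x$evaluations)) x$evaluations <- as.data.frame(x$evaluations)
    class(x) <- payload$class
  } else {
    x <- as.data.frame(x)
  }
  x
}
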