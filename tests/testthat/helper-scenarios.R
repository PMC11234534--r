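# Shared fixtures: scenarios are calibrated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_model <- function(spec, key) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- calibrate_scenario(spec)
  .fixture_cache[[key]]
}

# 24 equal-strength independent predictors, prevalence 0.174, c = 0.89
example_spec <- function() scenario_spec(0.174, 0.89, 24)
example_model <- function() cached_model(example_spec(), "example")

# the 12-predictor 5-true/7-noise reference DGM
ref_spec <- function(phi = 0.1, cstat = 0.85) main_study_spec(phi, cstat)

# brute-force all-pairs c-statistic (binary outcomes), ties scored 0.5
cstat_bruteforce <- function(pi_hat, y) {
  num <- 0; den <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    den <- den + 1
    num <- num + (pi_hat[i] > pi_hat[j]) + 0.5 * (pi_hat[i] == pi_hat[j])
  }
  num / den
}

# brute-force Harrell c-index over comparable pairs under right censoring
cindex_bruteforce <- function(lp, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable: the smaller observed time is an event
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(first)) next # tied times: skip (no order information used here)
    if (event[first] == 0) next
    other <- if (first == i) j else i
    den <- den + 1
    num <- num + (lp[first] > lp[other]) + 0.5 * (lp[first] == lp[other])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
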