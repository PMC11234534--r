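## Internal numerical helpers: quadrature, rounding, Monte Carlo summaries.

.quad <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights for integrals against exp(-x^2), cached per order.
gh_rule <- function(n = 120L) {
  key <- as.character(n)
  if (is.null(.quad[[key]])) .quad[[key]] <- pracma::gaussHermite(n)
  .quad[[key]]
}

# Gauss-Legendre rule on [-1, 1], cached.
gl_rule <- function(n = 128L) {
  key <- paste0("gl", n)
  if (is.null(.quad[[key]])) .quad[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .quad[[key]]
}

# E[g(eta)] for eta ~ N(mu, sigma^2) by Gauss-Hermite quadrature.
gh_expect <- function(g, mu, sigma, n_nodes = 120L) {
  r <- gh_rule(n_nodes)
  sum(r$w * g(mu + sqrt(2) * sigma * r$x)) / sqrt(pi)
}

# direct form is measurably faster than plogis in the replicate loops
expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) stats::qlogis(p)

# x*log(x) + (1-x)*log(1-x) evaluated stably from the logit scale
entropy_from_lp <- function(eta) {
  lp <- stats::plogis(eta, log.p = TRUE)
  lq <- stats::plogis(-eta, log.p = TRUE)
  exp(lp) * lp + exp(lq) * lq
}

#' Round a raw sample size to the 10-grid
#'
#' Sample sizes from the closed-form criteria are reported on a grid of 10
#' participants: `"nearest10"` (used for grid tables) rounds half away from
#' zero, `"up10"` (used for user-facing recommendations) always rounds up.
#'
#' @param n_raw Positive real sample size.
#' @param mode `"nearest10"` or `"up10"`.
#' @return Integer multiple of 10.
#' @examples
#' round_n(622.3, "up10")      # 630
#' round_n(6234.9, "nearest10") # 6230
#' @export
round_n <- function(n_raw, mode = c("nearest10", "up10")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(n_raw), n_raw > 0)
  if (mode == "nearest10") as.integer(floor(n_raw / 10 + 0.5) * 10)
  else as.integer(ceiling(n_raw / 10) * 10)
}

#' Monte Carlo standard error of a simulation summary
#'
#' @param values Numeric vector of per-replicate values (length at least 2).
#' @return Sample standard deviation divided by the square root of the number
#'   of replicates.
#' @export
mcse <- function(values) {
  stopifnot(length(values) >= 2)
  stats::sd(values) / sqrt(length(values))
}

# Independent substream seeds derived from a master seed (kept below 2^31).
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

check_probability <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a probability in %s", name,
                        if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}
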