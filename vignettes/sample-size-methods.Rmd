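---
title: "Sample size for risk prediction models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size for risk prediction models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sampsizesim)
```

## The problem

A clinical risk prediction model — say, a logistic regression for in-hospital
mortality — fitted on too small a development sample will be overfitted: its
extreme predictions are too extreme, and its apparent performance will not be
reproduced in new patients. Two widely used closed-form criteria translate
anticipated features of the development data into a minimum sample size:

* the **calibration criterion**, which controls the expected degree of
  overfitting. If the model were refitted on many samples of size $n$ and
  each fit validated on effectively infinite data, the average calibration
  slope (the coefficient $\alpha_1$ in the validation regression
  $\operatorname{logit} P(y=1) = \alpha_0 + \alpha_1\hat\eta$) should equal a
  target $S$, conventionally $0.9$. Via the heuristic shrinkage relation
  $S = (\Delta\chi^2 - p)/\Delta\chi^2$ this gives
  $$n = \frac{p}{(S-1)\log\left(1 - R^2_{CS}/S\right)},$$
  where $p$ is the number of predictor parameters and $R^2_{CS}$ the
  Cox–Snell $R^2$ of the anticipated model;

* the **MAPE criterion**, which controls the expected mean absolute error of
  the predicted probabilities against the truth,
  $$n = \exp\!\left(\frac{-0.508 + 0.259\log\phi + 0.504\log p - \log m}{0.544}\right),$$
  with $\phi$ the outcome prevalence and $m$ the target expected MAPE
  (commonly $\phi/10$).

The heuristic shrinkage relation is only accurate for modest model strength.
For strong models (c-statistic $\gtrsim 0.8$) the calibration criterion can
understate the required size substantially — by a factor of two or more at
$c = 0.9$ — while the MAPE criterion tends to overshoot. This package
therefore implements, alongside the closed forms (`rvs1_n()`, `rvs2_n()`), a
Monte Carlo engine that *measures* the distribution of the calibration
slope, c-statistic and MAPE at any candidate size
(`evaluate_performance()`), and a stochastic bisection search that finds the
size actually achieving the target expectation (`find_n_for_cs()`,
`find_n_for_mape()`).

## Calibrating the data-generating model

All simulation rests on one modelling assumption: across the population the
true linear predictor $\eta = \beta_0 + \beta^T x$ is normally distributed,
$\eta \sim N(\mu, \sigma^2)$. Under this assumption the anticipated
prevalence and c-statistic pin down the two moments:

$$\phi = E[\operatorname{expit}(\eta)], \qquad
  c = \frac{E\left[\operatorname{expit}(\eta_1)\,(1-\operatorname{expit}(\eta_0))\,
      1\{\eta_1 > \eta_0\}\right]}{\phi(1-\phi)},$$

with $\eta_0, \eta_1$ i.i.d. copies. `solve_lp_distribution()` solves this
system by nested one-dimensional root-finding (the prevalence is strictly
increasing in $\mu$ at fixed $\sigma$, and the c-statistic strictly
increasing in $\sigma$ after re-solving $\mu$), with both residuals required
below $10^{-6}$. The integrals are Gauss–Hermite quadrature with 120 nodes;
the inner truncated integral of the c-statistic uses a 128-node
Gauss–Legendre rule. These node counts were chosen so that quadrature error
is far below the calibration tolerance; the integrands are smooth
Gaussian-weighted functions, for which Gauss rules converge rapidly.

`coefficients_from_lp()` then realizes any predictor structure with these
moments: continuous predictors are standard normal with correlation matrix
$R$ and $\beta = f\gamma$ with $f = \sigma/\sqrt{\gamma^T R\gamma}$, so the
relative strengths $\gamma$ fix only the shape of the coefficients; for
independent binary predictors the Bernoulli variances replace $R$ and the
intercept absorbs the predictor means. Binary predictors make the linear
predictor skewed rather than normal; the package matches its mean and
variance, which in our checks (and in the sensitivity analyses that motivate
them) is sufficient for the expected calibration slope and MAPE to be
essentially unchanged across predictor structures at fixed $(\phi, c, n)$.

### Two Cox–Snell $R^2$ conversions

Two analytic routes from $(\phi, c)$ to $R^2_{CS}$ coexist in the field, and
the package implements both deliberately:

* `approx_r2cs()` assumes the *marginal* linear predictor is normal — the
  same assumption as the simulation engine — and computes
  $R^2_{CS} = 1 - \exp\{-2(\bar\ell_{model} - \bar\ell_{null})\}$ by
  quadrature. This is the exact population value for data generated by this
  package, and the value against which `r2cs_from_large_sample()` (a
  maximum-likelihood fit to $10^6$ simulated observations) is tested to
  agree within $0.01$.
* `r2cs_from_cstat()` assumes the linear predictor is normal with equal unit
  variance *within* the event and non-event groups, separated by
  $\sqrt2\,\Phi^{-1}(c)$. This is the conversion conventionally applied when
  a published c-statistic is plugged into the calibration criterion, and it
  is the default for `rvs1_n()`: with $\phi = 0.174$, $c = 0.89$, $p = 24$
  it gives $R^2_{CS} = 0.291$ and $n = 620$ (rounded up to the nearest 10),
  the standard worked example. The two conversions differ by well under
  $0.01$ in $R^2$ across the usual grid ($c \le 0.9$, $\phi \in
  [0.1, 0.5]$); we default to the binormal form for closed-form
  recommendations because that is what users comparing against published
  calculators expect, and keep the unconditional form as the engine-side
  ground truth.

EPV (events per variable, $n\phi/p$) is reported from the *unrounded* size,
matching the convention of the published grid tables; the rounded size is
used for the recommendation itself (`round_n()`, `"up10"` for user-facing
results and `"nearest10"` for tables).

## The Monte Carlo engine

`evaluate_performance(spec, n, n_sim, n_val, seed)` repeats, `n_sim` times:
draw a development sample of size $n$, fit the logistic model by maximum
likelihood, and measure on a fresh validation draw of size `n_val` the
calibration slope, the c-statistic (midrank estimator, ties scored 0.5,
identical to the all-pairs definition), and the MAPE against the known true
probabilities. Summaries carry Monte Carlo standard errors
(SD$/\sqrt{n_{sim}}$), the RMSD of the slope from 1 (a stability measure
combining bias and variance), and the tail probabilities $P(CS<0.8)$,
$P(CS<0.9)$ and $P(|\hat c - c| \le 0.02)$.

Numerical and design choices:

* **Defaults** `n_sim = 1000`, `n_val = 25000` keep the MCSE of the mean
  calibration slope near 0.0025 around the sizes the search visits;
  study-replication runs use 2000 and 100{,}000.
* **Validation sampling.** For continuous predictors, conditional on the
  fitted coefficients $(\hat\beta_0, \hat\beta)$ the pair
  $(\eta, \hat\eta)$ in a validation draw is exactly bivariate normal with
  $\mathrm{Var}(\eta) = \sigma^2$,
  $\mathrm{Var}(\hat\eta) = \hat\beta^T R \hat\beta$ and
  $\mathrm{Cov} = \beta^T R \hat\beta$. The engine therefore samples
  $(\eta, \hat\eta)$ directly instead of materialising an
  $n_{val} \times p$ predictor matrix — the distribution of every metric is
  identical (this is tested against the full-matrix route) and evaluation is
  roughly an order of magnitude faster. Binary predictors use the
  full-matrix route.
* **Seeding.** A master seed spawns one development and one validation
  substream per replicate. Evaluations at different $n$ under the same
  master seed reuse the same substreams (common random numbers), which makes
  the mean-CS-versus-$n$ curve smooth and is what lets a noisy bisection
  behave monotonically.
* **Degenerate fits.** Replicates with a single-class outcome, a
  non-converged fit, or quasi-separation (fitted probabilities numerically
  at 0/1, or exploding coefficients) are redrawn from the same replicate
  substream, keeping the estimand "models fitted by MLE" well defined; the
  redraw count is reported and a warning raised if it exceeds 1% of
  `n_sim`. A warning is also given when $n\phi < 2p$, where such failures
  become common.

## The sample-size search

`find_n_for_cs()` brackets the target starting from the closed-form
calibration size (halving/doubling as needed), then bisects the mean
calibration slope on a grid of 10 participants using common random numbers,
until the bracket collapses to one grid step. The returned size is the
smallest grid point whose mean CS reaches the target; if it misses the
target by more than `tol_cs` (default 0.005), one linear-interpolation
refinement across the final bracket is evaluated. With common random
numbers the entire evaluated curve shifts together, so the residual
uncertainty in the located size is roughly MCSE divided by the local slope
of the mean-CS curve — about $\pm 15$ participants at the defaults in the
worked example below. `find_n_for_mape()` is identical with the direction
reversed (mean MAPE decreases in $n$) and the bracket seeded from the MAPE
criterion; an extremely loose target that is already met at the smallest
size considered returns that lower bound with an explanatory note rather
than an error.

As a worked example (`n_sim = 1000`, `n_val = 25000`): for $p = 24$
equal-strength predictors, $\phi = 0.174$, $c = 0.89$, the calibration
criterion suggests $n = 620$, but the engine measures a mean calibration
slope of about $0.80$ there, with $P(CS < 0.8) \approx 0.5$ and
$P(CS < 0.9) \approx 0.87$; the search puts the size actually achieving an
expected slope of 0.9 at about $1300$, more than double, while the MAPE
target of 0.05 is reached already at about $630$ (the MAPE criterion's 800
is conservative here). Each search takes a few minutes on one CPU.

## Time-to-event outcomes

The survival module replaces the Bernoulli outcome with exponential survival
times $T_i \sim \mathrm{Exponential}(\lambda_0 e^{\eta_i})$ (constant
baseline hazard, proportional hazards) and administrative censoring at a
fixed time, calibrated by quadrature so that a prespecified proportion of
observations are events (`calibrate_censor_time()`). Model strength is the
concordance: for exponential pairs the censoring-free c-index has the closed
form $E[\operatorname{expit}(|\Delta|)]$, $\Delta \sim N(0, 2\sigma^2)$,
which `solve_sigma_cindex()` inverts for $\sigma$; the empirical Harrell
c-index (comparable pairs under right censoring) is computed through the
concordance machinery of the survival package. Development fits use the Cox
partial likelihood; the survival calibration slope is the coefficient of
$\hat\eta$ in a Cox model on validation data. The strength input for the
closed-form criterion is the Cox-model Cox–Snell $R^2$ estimated on a large
simulated sample (`r2cs_cox_large_sample()`), which grows with the event
proportion. Our property tests reproduce the qualitative findings for this
setting: the calibration criterion is about right at modest concordance with
half the observations censored, while at high concordance the expected
slope falls short of target — and further short the *fewer* observations
are censored. There is no survival-specific search; the binary machinery
carries over if needed.

## What the generator does and does not emulate

The generator emulates anticipated development data exactly as the
closed-form criteria conceive of them: predictors multivariate normal (or
independent binary), a correctly specified logistic (or exponential
proportional-hazards) outcome model, no missing data, no measurement error
and no variable selection. Passing tests therefore demonstrate properties
of the sample-size methodology under its own assumptions — they do not
certify behaviour under model misspecification, selection procedures or
penalised estimation, which are outside this package's scope.

## Problem sizes used in the test suite

The packaged tests replicate the study's quantitative findings at reduced
scale, chosen to keep the full suite to minutes while leaving Monte Carlo
error bands informative: searches re-run at `n_sim` of 500–1000 and
`n_val = 25000` for the headline numbers, property checks at `n_sim` of
100–200 with `n_val` of 4000–8000, and large-sample identities (prevalence
and c-statistic recovery, the $R^2_{CS}$ agreement) at $10^6$ simulated
observations. All stochastic assertions state their tolerance as a multiple
of the measured MCSE plus the print precision of the value they reproduce.

## Known limitations

* The calibration of $(\mu, \sigma)$ assumes a normal marginal linear
  predictor; with binary predictors only the first two moments are matched.
* The closed-form criteria are reproduced as printed, including their
  empirically fitted MAPE coefficients; no attempt is made to re-derive
  them.
* The search optimises one criterion at a time; users wanting both targets
  run both searches and take the maximum.
* Stochastic search results carry residual Monte Carlo uncertainty of order
  one to a few grid steps; the full evaluation trace (with MCSEs) is
  returned so users can judge it.
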