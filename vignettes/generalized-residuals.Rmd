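---
title: "Assessing factor-model fit with generalized residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing factor-model fit with generalized residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

The linear normal common factor model assumes that an observed vector of
continuous manifest variables (MVs) `x` arises as

    x = nu + Lambda eta + e,    eta ~ N(0, Phi),   e ~ N(0, diag(Psi)),

so that marginally `x ~ N(nu, Lambda Phi Lambda' + diag(Psi))`. Conventional
goodness-of-fit diagnostics (the likelihood-ratio chi-square, CFI, TLI, SRMR,
RMSEA) judge the model through the recovery of means and covariances only.
Two substantive assumptions are invisible to them: the multivariate normality
of the latent vector `eta`, and the linearity/homoscedasticity of each MV's
conditional distribution given `eta`. A latent distribution consisting of two
negatively correlated subgroups, for instance, can reproduce the marginal
means and covariances of a bivariate normal exactly, while making the
estimated latent correlation completely misleading. Similarly, a quadratic
conditional mean or a variance that grows with the latent trait leaves the
marginal residual means and variances of a one-factor model at exactly zero.

`grfa` implements fit assessment through *generalized residuals*: for any
summary quantity `e(x; theta)`, compare its sample average against its
model-implied expectation at the ML estimate. With summaries chosen
conditionally on latent values, this yields localized diagnostics of exactly
the assumptions that mean-and-covariance fit measures cannot see.

## The residual machinery

Let `e(x; theta)` be a `k`-vector of summaries, `e_bar` its sample average
over the `n` observations, and `E(theta)` its population expectation under
the model. A smooth transformation `g` (identity, or elementwise ratios)
gives the transformed residual

    r = g(e_bar) - g(E(theta_hat)),

which is asymptotically normal under correct specification:
`sqrt(n) r -> N(0, Omega)` with

    Omega = J (Sigma_e - C' I^{-1} C) J',

where `J` is the Jacobian of `g`, `Sigma_e` the covariance of `e`, `C` the
cross-covariance between the per-observation score vector and `e`, and `I`
the per-observation expected information. The subtraction accounts for the
sampling variability of the plugged-in ML estimate; dropping it (as the
fixed-parameter variant does) would overstate the variance of residuals of
estimated models.

Three estimation choices matter and are deliberate:

* **Monte-Carlo moments.** `Sigma_e` and `C` are estimated from `R`
  simulated draws of the fitted marginal model ([`mc_moments()`]), not from
  the sample: sample-based moment plug-ins inflate Type I error at small
  `n`. The draw count defaults to `R = 50000` and is always seeded and
  logged. Where the model expectation has a closed form — all three turnkey
  tests below — the closed form is used for the residual's model-implied
  side, and Monte Carlo supplies only the covariances.
* **Expected information.** `I` is computed analytically from the normal
  marginal model (derivative arrays of the mean and covariance in the packed
  parameter ordering `nu`, free loadings, free factor covariance, error
  variances); an MC covariance-of-scores estimator of the same matrix is
  retained as an internal cross-check.
* **Eigenvalue clipping.** `Omega` is symmetrized and small negative
  eigenvalues — MC noise in near-degenerate directions, strongly amplified
  by ratio Jacobians near the latent tails — are clipped to zero. The
  clipping threshold is judged against the scale of the *uncorrected*
  variance, because a perfectly recovered moment (for example, the saturated
  mean structure) legitimately has a corrected variance of zero. Gross
  indefiniteness still errors. Clipping can only make pointwise tests
  conservative, never anti-conservative.

## Test statistics

A single residual is standardized to `z = sqrt(n) r / omega^{1/2}`, compared
against the standard normal (`|z| > 1.96` flags misfit at the 5% level). For
a residual vector, the overall statistic is the quadratic form
`T = n r' W r` with weight matrix

    W = U Dtilde U',

where `U D U'` is the eigendecomposition of `Omega` (eigenvalues sorted
descending, ties kept in stable index order) and `Dtilde` inverts only the
`s` largest eigenvalues. Under correct specification `T` is asymptotically
chi-square with `s` degrees of freedom for *any* admissible `s`; fixing a
small `s` (default 2, a required and logged parameter) avoids the numerical
rank determination that makes Moore-Penrose-weighted statistics unstable —
the pseudoinverse is recovered exactly when `s` equals the rank. Retained
degrees never split a degenerate eigenspace in our tests, so `T` is
invariant to eigen-basis ambiguity.

## The three worked tests

All three evaluate summaries on a grid of latent values `eta_q`
([`make_grid()`]).

* **Latent-density normality** ([`lv_density_test()`]): the summary is the
  posterior density `f(eta_q | x)`, whose model expectation is exactly the
  latent density `phi(eta_q; 0, Phi)` by Bayes' theorem. The sample average
  of posterior densities is a density estimate of the latent distribution;
  its discrepancy from the implied normal reveals mixtures, skewness, or
  kurtosis that marginal moments mask. Identity transform.
* **MV-level linearity** ([`mv_linearity_test()`]): stacks
  `a_q = x_j f(eta_q | x)` and `b_q = f(eta_q | x)`; the elementwise ratio
  of their averages estimates the conditional mean `E[x_j | eta_q]`, which
  the model asserts equals `nu_j + lambda_j' eta_q`. An untransformed
  variant ([`mv_direct_mean_test()`]) targets the product of the conditional
  mean and the latent density directly; it needs no ratio but is
  correspondingly sensitive to latent-density misspecification, so the ratio
  form is the default.
* **MV-level homoscedasticity** ([`mv_homoscedasticity_test()`]): replaces
  the numerator by `(x_j - nu_j - lambda_j' eta_q)^2 f(eta_q | x)`; the
  ratio estimates the conditional variance, constant at `psi_j` under the
  model.

The posterior density appearing in all three summaries is the closed-form
conditional normal with covariance `(Phi^{-1} + Lambda' Psi^{-1}
Lambda)^{-1}` — free of `x` — rather than a numerical Bayes quotient; the
quotient identity is enforced by a test to 1e-10.

**Grids.** Default for one latent dimension: 31 evenly spaced points on
[-3, 3] for the pointwise statistics, with the overall statistic built on 11
evenly spaced sub-points on [-2, 2]. The narrower subgrid is deliberate:
beyond two latent standard deviations the latent density carries under 5% of
the mass, ratio denominators approach zero, and pointwise calibration
degrades — extreme-grid deviations are expected there and carry no
practical information. For two dimensions, 7 points per axis on [-3, 3]^2
with the full 49-point grid as subgrid. Ratio-based tests additionally flag
as unusable any grid point where the model-implied latent density falls
below 1e-4 of its grid maximum; an overall statistic whose subgrid touches
such points errors rather than silently degrading.

## Estimation

[`fa_fit()`] maximizes the normal marginal likelihood from sufficient
statistics (cost independent of `n` after one data pass) over an
unconstrained reparameterization: log error variances, atanh-correlations
(unit-factor-variance identification) or a log-Cholesky factor
(anchor-loading identification) for `Phi`, raw loadings and intercepts.
Positivity is structural, so Heywood cases cannot occur. A deterministic
principal-component start feeds BFGS, followed by Fisher-scoring polish with
step halving until the total-score gradient falls below 1e-5, a default in
line with what standard SEM software aims for. Convergence is
recorded as three explicit flags — gradient, positive-definite information,
positive error variances — and rank-deficient expected information raises an
identification error instead of returning a silent answer. For the atanh
parameterization with more than two factors positive definiteness is not
automatic; non-positive-definite proposals are rejected during optimization
(the bundled study designs use at most two factors).

## What the synthetic designs emulate

[`study1_config()`] reproduces a two-factor independent-cluster structure:
20 MVs in two clusters of 10, zero intercepts, communalities cycling
0.3/0.5/0.7 (low to high), latent correlation 0.2. Its misspecified
condition replaces the bivariate normal latent density with a two-component
mixture moment-matched *exactly* (closed-form constraint, not numerical) to
mean zero and the same covariance — equal weights, component means at
+/-(0.7, 0.7), within-component covariance [[0.51, -0.29], [-0.29, 0.51]],
so the two subgroups have negatively *correlated* latent variables while the
pooled correlation remains +0.2. Mean-and-covariance diagnostics are blind
to this by construction; the latent-density test is not.

[`study2_config()`] reproduces a one-factor design with 10 MVs crossing
linear/quadratic conditional means with constant/log-linear conditional
variances (kinds LMCV, QMCV, LMLV, QMLV). The coefficient magnitudes are
free design choices; our defaults are `lambda = sqrt(0.5)`
for all MVs (communality 0.5), `beta3 = log(0.5)` and `beta4 = 0.5` for the
log-linear variance (matching the constant variance at `eta = 0`), and
`beta2 = 0.1` for the quadratic mean. The choice of `beta2` follows a
first-order/second-order argument: the linearity test sees the quadratic
term at first order (bias `beta2 (eta^2 - 1)` in the conditional mean),
while the homoscedasticity test sees it only at second order (squared bias
inflating the apparent conditional variance). A coefficient of 0.1 keeps the
second-order contamination near sampling resolution at `n = 1000` while the
first-order curvature is reliably detected — which is what produces the
test-family selectivity the framework is designed for. The selectivity is
directional, not absolute: a sufficiently strong mean misspecification will
eventually inflate the variance diagnostics too.

[`replicate_rates()`] is the replication harness: generate, fit the linear
normal analysis model (never the generating truth), test, and aggregate
rejection proportions with the normal-approximation Monte-Carlo band around
the nominal level. Replication `r` under master seed `m` uses data seed
`m + 2r` and MC seed `m + 2r + 1`, so chunked runs reproduce a single run
exactly.

What passing these simulations does *not* show: the generators draw exactly
normal errors and independent observations, so the studies say nothing about
robustness to non-normal measurement error, dependent sampling, or missing
data — all outside the model class. Sample-size-free effect sizes are not
provided; like all consistent fit tests, these reject trivial misfit at
large enough `n`.

## Problem sizes and numerical choices

The bundled statistical checks run at reduced desk scale, chosen to keep the
full suite in minutes while leaving the Monte-Carlo bands meaningful: size
and calibration studies use 200 replications at `n = 500` with `R = 2000`
MC draws; power and selectivity use 100 replications per cell; the
asymptotic-covariance oracle compares the analytic `Omega` against the
empirical covariance of `sqrt(n) r` over 1000 parametric-bootstrap
replications of a one-factor five-MV model at `n = 1000` (15% relative
tolerance on diagonals). The identity oracles (posterior-density expectation
equals the latent density; conditional-moment ratios equal the linear mean
and constant variance) run at `R = 1e5` within four MC standard errors.

Other defaults: rank tolerance for admissible `s` is `1e-10` of the largest
eigenvalue (it gates only the `s <= rank` check, never the statistic
itself); the `T` scaling uses `n`, matching the `sqrt(n)` asymptotics;
pointwise variances below `1e-12` mark the statistic unusable rather than
producing an unstable `z`.

## Limitations

Outer-product grids are refused for latent dimension above three; partially
marginalized residuals for high dimensions, pairwise local-independence
residuals, effect-size measures, missing data, categorical MVs, and
non-ML estimators are out of scope. The ratio-form MV tests assume the
latent density is approximately correct; when it is not, their posterior
weights are computed under a wrong measure (the direct-mean variant makes
that sensitivity visible by comparison).
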