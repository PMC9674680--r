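---
title: "Methods: Poisson mixture calibration surfaces and dose posteriors for the gamma-H2AX assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson mixture calibration surfaces and dose posteriors for the gamma-H2AX assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(h2axdose)
```

## The model

Counts of gamma-H2AX foci per cell are overdispersed: peripheral blood
mononucleated cells are a mixture of leukocyte subsets with plausibly
different radiosensitivity, so a single Poisson law underfits the spread.
`h2axdose` models a cell's foci count at dose $d$ (Gy) and post-irradiation
time $t$ (h) as a finite Poisson mixture

$$ y \mid \omega, \lambda \sim \sum_{k=1}^K \omega_k\,
   \mathrm{Poisson}\!\left(\lambda_k(d, t)\right), \qquad
   \lambda_k(d,t) = c_k\,t^{u_k} + a_k\,t^{v_k}\,d , $$

with weights $\omega_k \in (0,1)$, $\sum_k \omega_k = 1$. Each component
mean is a dose--time surface: $c_k t^{u_k}$ is the spontaneous (zero-dose)
rate and $a_k t^{v_k}$ the dose slope, both decaying in time when the
exponents are negative — matching the repair kinetics of radiation-induced
double-strand breaks, which peak around half an hour after exposure and
approach background by 24--48 h. At any fixed $t$ the population mean is
affine in dose,

$$ \mu(d \mid t) = \alpha_t + \beta_t d, \qquad
   \alpha_t = \sum_k \omega_k c_k t^{u_k}, \qquad
   \beta_t  = \sum_k \omega_k a_k t^{v_k} . $$

Positivity of $a_k$ and $c_k$ is enforced structurally (they are optimized
on the log scale) because $\lambda_k$ must be a valid Poisson mean over the
whole design region $d \in [0,3]$, $t \in [0.5, 24]$; the exponents are
unconstrained in sign. A variant with one shared exponent $u$ across
components is available (`mixture_spec(K, shared_u = TRUE)`); the
four-component shared-$u$ model has $3 + 12 + 1 = 16$ free parameters
(weights count $K - 1$ under the simplex constraint).

## Priors, fitting, and the Laplace approximation

The weights get Perks' prior, the symmetric Dirichlet with concentration
$1/K$; the surface coefficients get independent uniform priors. Because no
admissible ranges are canonical for the coefficients, the uniform supports
are a generous box in the optimization coordinates, chosen once from the
physics of the assay (at most a few tens of foci per cell, kinetics playing
out over a day): $\log a_k, \log c_k \in [-10, 5]$ and $u, v_k \in [-5, 2]$.
All are user-overridable in `prior_spec()`.

Optimization works in an unconstrained *free parametrization*: additive
log-ratio transformed weights (reference component $K$), $\log a_k$,
$\log c_k$, and raw exponents. This makes the Gaussian approximation
well-defined without boundary effects from the simplex or positivity
constraints; the hand-off file records the coordinate names so consumers can
invert the map. `map_fit()` maximizes the log posterior by multi-start
L-BFGS-B: a deterministic start from a single-surface least-squares moment
fit, plus random starts that jitter coefficients by up to roughly $\pm 50\%$
and draw weights from a flat Dirichlet — mixture likelihoods are multimodal
and the label-switching symmetry alone creates $K!$ equivalent modes. Fitted
components are reported in a canonical order, ascending in the dose slope
$a_k$ (the coefficient most likely to separate radiosensitivity subsets).
The inner mixture sum of the log-likelihood uses log-sum-exp; component
means reach $\sim 25$ foci at high dose and short time, where naive pmf
products underflow.

The Laplace approximation
$\pi(\omega, \theta \mid y) \approx N_p(\phi^*, \hat\Sigma)$ takes
$\hat\Sigma$ as the inverse of the negative Hessian of the log posterior at
the mode, computed by central finite differences with per-coordinate step
$10^{-4}(1 + |\phi^*_j|)$ and symmetrized. Eigenvalues of the curvature that
are non-positive but within $10^{-6}$ of the dominant one are floored with a
warning (numerical noise at a flat mode); anything worse is an error naming
the offending coordinate directions — which is exactly what happens when the
design cannot identify the parameters, e.g. data from a single scoring time,
where $t^{u}$ is perfectly confounded with $c$.

Mixture order is chosen by AIC, $2p - 2\log L$ at the MAP (the flat
coefficient priors make the MAP essentially the MLE), via `select_model()`.
For cross-checking the Gaussian approximation the package ships an adaptive
random-walk Metropolis-within-Gibbs sampler (`mcmc_sample()`); the surface
parametrization admits no conjugate structure, so a pure Gibbs sampler is
not available, and the sampler's role is validation, not production.

The calibration hand-off is one JSON file: model structure, parametrization,
the $p$ modal coefficients and the $p \times p$ covariance — for the
$K = 4$ shared-$u$ family, $16 + 136 = 152$ numbers. A covariance over all
$K$ weights would be singular under the simplex constraint; reporting the
unconstrained-space covariance (with its recorded parametrization) keeps the
matrix full-rank and is what the estimation side consumes.

## From the full posterior to the calibration line

`alpha_beta_posterior()` collapses the Laplace posterior to the line
coefficients at any fixed $t$ by the first-order delta method:

$$ \pi(\alpha_t, \beta_t \mid y) \approx
   N_2\!\left(g(\phi^*),\; \nabla g\, \hat\Sigma\, \nabla g^\top\right), $$

with $g = (g_1, g_2)$ the map from the free coordinates to
$(\alpha_t, \beta_t)$. The gradient is analytic (the closed form is simple
and avoids step-size tuning); the test suite cross-checks it against finite
differences. No second-order correction is applied: the approximation is
first-order by design, and its accuracy is quantified rather than patched —
the pushforward mean of $g$ under $N_p(\phi^*, \hat\Sigma)$ exceeds
$g(\phi^*)$ by $\tfrac12\mathrm{tr}(\nabla^2 g\, \hat\Sigma)$, about
$10^{-3}$ foci at the reference design, which is negligible against the
posterior spread of $(\alpha_t, \beta_t)$ but detectable by a large
Monte-Carlo sample. The unit tests verify the implementation against this
exact second-order identity.

## Dose estimation under time uncertainty

The estimating laboratory sees only aggregate data: mean foci count
$\bar x$, standard deviation $s$, and cell count $n$. The patient's expected
count is modelled nonparametrically as $\mu \sim N(\bar x, s^2/n)$,
independent of the calibration posterior (different data sources). Inverting
the calibration line gives $d \mid t = (\mu - \alpha_t)/\beta_t$.

Uncertainty in the exposure time enters through a prior $\pi(t)$: uniform on
$(t_{lo}, t_{hi})$, or a scaled beta
$t = t_{lo} + (t_{hi} - t_{lo})\,B$, $B \sim \mathrm{Beta}(\alpha, \beta)$ —
symmetric shapes like $(5,5)$ or $(100,100)$ express increasing confidence
that the exposure happened near the interval's centre.

Two routes to the marginal dose posterior $\pi(d \mid y, x)$:

* **Simulation** (`simulate_dose_posterior()`): repeatedly draw
  $t^* \sim \pi(t)$, then $(\alpha_{t^*}, \beta_{t^*})$ from the bivariate
  normal above, then $\mu^* \sim N(\bar x, s^2/n)$, and record
  $d^* = (\mu^* - \alpha_{t^*})/\beta_{t^*}$; at least 10,000 draws
  (default), $10^5$ in the package's own checks. Draws with
  $\beta_{t^*} \le 0$ are flagged invalid and a warning fires if they exceed
  1%.
* **Quadrature** (`dose_posterior_grid()`): integrate
  $\pi(d, t \mid y, x) = \pi(d \mid t, y, x)\,\pi(t)$ over $t$ with 64-node
  Gauss--Legendre quadrature (the integrand is smooth in $t$, so the rule
  converges spectrally). The conditional $\pi(d \mid t, y, x)$ is computed
  exactly as the density of a ratio of correlated normals (Hinkley's
  formula): numerator $\mu - \alpha_t$ with the patient's sampling variance
  folded in, denominator $\beta_t$, correlation induced by
  $\mathrm{cov}(\alpha_t, \beta_t)$. A degenerate-denominator branch
  ($\mathrm{sd}(\beta_t) \to 0$) reduces to the normal density. The dose
  grid defaults to the conditional means $\pm 10$ conditional standard
  deviations (2001 points); if the grid captures less than 99% of the mass
  the function refuses rather than silently renormalizing a truncated
  density.

Negative dose draws are *retained* in the raw sample — the ratio can go
negative whenever $\mu^* < \alpha_t$, and dropping them would distort the
stated ratio-of-normals distribution. Truncation of the *summaries* to
$d \ge 0$ is an explicit user switch (`truncate = TRUE`). Summaries report
the posterior mean, the median, and an equal-tailed credible interval at a
default level of 0.95 (both mean and median are printed because practice
varies in which one a laboratory quotes; the level is user-settable since
reporting conventions differ).

Both routes are deterministic given the seed; every CLI command echoes its
seed in the output so a run is reproducible from its output file alone.

## The synthetic-data generator

`generate_calibration_data()` draws per-cell counts exactly from the
generative model: a component from the weights, then a Poisson count at that
component's surface mean, for every cell of every (dose, time) condition.
The default design mirrors the calibration layout the method targets —
doses $\{0, 0.5, 1, 2, 3\}$ Gy, times $\{0.5, 1, 2, 4, 24\}$ h, 500 cells
per condition. The reference parameter set
(`example_mixture_params()`: $K = 2$, $\omega = (0.6, 0.4)$, shared
$u = -0.3$, $v = (-0.5, -0.9)$, $c = (0.4, 0.8)$, $a = (3, 6)$) was chosen
once to give realistic magnitudes — about 0.5--1 spontaneous focus per cell
and $\sim 25$ foci at 3 Gy scored half an hour after exposure — and is a
fixture, not an estimate from any experiment.

What the generator does *not* emulate: scorer/microscope detection error,
donor-to-donor variability, zero inflation beyond what the mixture induces,
and any departure of real foci kinetics from the $t$-power-law surface.
Passing tests therefore demonstrate internal consistency of the inference
machinery and its calibrated frequency properties *under the model*, not the
adequacy of the surface family for any particular laboratory's data.

`generate_patient_sample()` draws a patient's cells at a true (dose, time)
and returns both the aggregate summary (all the estimation side may see) and
the raw counts, so the aggregate-only interface is testable as a boundary.

## Problem sizes and numerical choices in the shipped checks

The package's own verification uses: one cached calibration fit at the full
reference design (12,500 cells) reused across checks; $10^5$-draw
Monte-Carlo pushforwards against the delta method; nine
simulation-vs-quadrature scenarios (three exposure scenarios crossed with
uniform, Beta(5,5) and Beta(100,100) time priors) compared by
total-variation distance and quantiles; 50-replicate coverage of the
$(\alpha_t, \beta_t)$ Laplace intervals and 25-replicate end-to-end dose
coverage, fitted with two optimizer starts per replicate (the moment-based
start makes more starts redundant for well-separated truth); and a
4,000-iteration MCMC run against the Laplace route, compared on the
downstream dose estimates. A scaled-down two-component model keeps these
replicated fits cheap while exercising every code path a larger $K$ would.

## Known limitations

* The method targets acute, whole-body, low-LET exposure; high-LET damage
  kinetics and chronic or gradient exposures violate the surface model.
* The Laplace + delta pipeline is first-order: posteriors must be
  unimodal and approximately Gaussian in the free coordinates, which holds
  for well-identified designs with hundreds of cells per condition but can
  fail for sparse designs (see the single-time confounding error above).
* AIC selects among Poisson mixtures only; negative-binomial or
  zero-inflated families are out of scope.
* The patient summary model $\mu \sim N(\bar x, s^2/n)$ relies on the
  central limit theorem, i.e. on $n$ in the hundreds of cells.
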