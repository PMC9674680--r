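# h2axdose

Bayesian radiation biodosimetry from γ-H2AX foci counts, with uncertainty
about the time since exposure.

## The problem

After a radiological accident, the absorbed dose of a potentially exposed
person must be estimated quickly from a biological marker. Counts of
γ-H2AX foci — microscopically visible clusters of phosphorylated histone
H2AX at DNA double-strand breaks — rise with absorbed dose but also decay
over the hours following exposure, and the exact exposure time is rarely
known. `h2axdose` implements a two-laboratory workflow for this setting:

* **Laboratory 1 (calibration).** Per-cell foci counts from blood irradiated
  in vitro at known doses *d* (Gy) and scored at known post-irradiation
  times *t* (h) are fitted with a K-component Poisson mixture,

  y ~ Σₖ ωₖ Poisson(λₖ(d, t)),  λₖ(d, t) = cₖ·t^uₖ + aₖ·t^vₖ·d,

  which captures the overdispersion of foci counts (e.g. differentially
  radiosensitive leukocyte subsets). With Perks' Dirichlet prior
  (concentration 1/K) on the weights and uniform priors on the surface
  coefficients, the posterior of the parameters is approximated by
  **Laplace's method**: a p-dimensional normal N(φ*, Σ̂) centred at the MAP
  with covariance the inverse negative Hessian. The mixture order K is
  chosen by AIC. For the four-component shared-u family this hand-off is
  16 coefficients + 136 covariance values = 152 numbers in one JSON file.

* **Laboratory 2 (estimation).** At fixed t, the expected count is affine in
  dose: μ(d | t) = α_t + β_t·d with α_t = Σₖ ωₖcₖt^uₖ, β_t = Σₖ ωₖaₖt^vₖ.
  The delta method turns the Laplace posterior into a bivariate normal for
  (α_t, β_t). Given a patient's aggregate foci summary (mean x̄, sd s,
  n cells; the expected count is modelled as μ ~ N(x̄, s²/n)) and a prior
  π(t) on the unknown exposure time (uniform or scaled beta on an
  interval), the dose posterior π(d | data) is obtained either by
  Monte-Carlo simulation of d = (μ − α_t)/β_t (≥ 10,000 draws) or by
  numerical integration over t of the exact ratio-of-correlated-normals
  conditional density. Reported: posterior mean, median and equal-tailed
  credible interval.

## Worked example

```r
library(h2axdose)

## Laboratory 1: calibrate on a simulated experiment at the reference design
params <- example_mixture_params()                 # K = 2 reference mixture
data   <- generate_calibration_data(params, design_grid(), seed = 421)
fit    <- map_fit(data, mixture_spec(2, shared_u = TRUE), n_starts = 4, seed = 422)
lap    <- laplace_approx(fit, data)
print(alpha_beta_posterior(lap, t = 4))
#> Calibration line at t = 4 h:
#>   alpha = 0.3739 (sd 0.0125), beta = 1.5944 (sd 0.0171), corr -0.508

## Laboratory 2: a patient exposed to 0.75 Gy, scored ~4 h later
pat <- generate_patient_sample(params, 0.75, 4, n_cells = 500, seed = 5)$summary
dp  <- simulate_dose_posterior(lap, pat, time_prior("uniform", 3, 5),
                               m = 1e5, seed = 7)
print(dp)
#> Dose posterior (simulate, m = 100000):
#>   mean 0.754 Gy, median 0.755 Gy, 95% CI (0.597, 0.918) Gy
dg  <- dose_posterior_grid(lap, pat, time_prior("uniform", 3, 5))
print(dg)
#> Dose posterior (integrate, 64 time nodes):
#>   mean 0.754 Gy, median 0.755 Gy, 95% CI (0.597, 0.917) Gy
```

The posterior mean of about 0.75 Gy and its 95% interval cover the true
0.75 Gy exposure; the simulation and quadrature routes agree to three
decimals.

The same steps run from a shell through the thin CLI wrapper:

```sh
Rscript inst/cli/biodose.R simulate  --params params.yaml --seed 1 --out calib.csv
Rscript inst/cli/biodose.R calibrate --data calib.csv --K 2 --seed 2 --out calibration.json
Rscript inst/cli/biodose.R estimate  --calibration calibration.json \
    --mean 4.072 --se 0.230 --n-cells 500 \
    --time-prior uniform --t-lo 3 --t-hi 5 --seed 3 --out estimate.csv
```

## Documentation

The methods vignette (`vignettes/dose-estimation-methods.Rmd`) describes
the model, priors, numerical choices, the synthetic-data generator and the
known limitations in detail.
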