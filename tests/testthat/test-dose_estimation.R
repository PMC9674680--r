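test_that("time-prior draws have the right support and moments", {
  u <- time_prior("uniform", 3, 5)
  du <- sample_time_prior(u, 1e5, seed = 11)
  expect_true(all(du > 3 & du < 5))
  expect_lt(abs(mean(du) - 4), 0.01)
  # scaled Beta(100, 100) on (0.25, 0.75): sd = 0.5 * sqrt(1 / (4 * 201))
  b <- time_prior("beta", 0.25, 0.75, shape1 = 100, shape2 = 100)
  db <- sample_time_prior(b, 1e5, seed = 12)
  expect_lt(abs(sd(db) - 0.5 * sqrt(100 * 100 / (200^2 * 201))), 5e-4)
  b5 <- time_prior("beta", 3, 5, shape1 = 5, shape2 = 5)
  db5 <- sample_time_prior(b5, 2e4, seed = 13)
  expect_true(all(db5 > 3 & db5 < 5))
  expect_lt(abs(mean(db5) - 4), 0.02)
  # densities integrate to 1 over the support
  for (pr in list(u, b, b5)) {
    gr <- seq(pr$t_lo, pr$t_hi, length.out = 4001)
    dens <- dtime_prior(pr, gr)
    expect_equal(sum(diff(gr) * (head(dens, -1) + tail(dens, -1)) / 2), 1,
                 tolerance = 1e-6)
  }
})

test_that("inverse dose relation is the exact ratio, negative doses permitted", {
  expect_equal(dose_given_t(mu = 1, alpha = 1, beta = 2), 0)
  expect_equal(dose_given_t(mu = 5, alpha = 1, beta = 2), 2)
  expect_equal(dose_given_t(mu = 0.5, alpha = 1, beta = 2), -0.25)
  expect_error(dose_given_t(1, 1, 0), "zero")
})

test_that("degenerate posterior, patient and prior give a point-mass dose", {
  fx <- cached_fit()
  lap0 <- fx$laplace
  lap0$cov <- 0 * lap0$cov
  pat <- patient_summary(mean_foci = 2, sd_foci = 0, n_cells = 100)
  pr <- time_prior("uniform", 4, 4)   # point prior
  dp <- simulate_dose_posterior(lap0, pat, pr, m = 10000, seed = 21)
  ab <- alpha_beta_point(lap0$params, 4)
  d0 <- unname((2 - ab[1, "alpha"]) / ab[1, "beta"])
  expect_true(all(abs(dp$draws - d0) < 1e-12))
  s <- dp$summary
  expect_equal(s$mean, d0)
  expect_equal(s$ci_lo, d0)
  expect_equal(s$ci_hi, d0)
})

test_that("ratio-of-normals density: constant-denominator limit and normalization", {
  # var(beta) -> 0: density collapses to a normal in (mu - alpha) / beta
  z <- seq(-1, 3, length.out = 801)
  f <- dratio_normal(z, mu1 = 1.2, sigma1 = 0.4, mu2 = 1.6, sigma2 = 0,
                     rho = 0)
  expect_equal(f, dnorm(z, 1.2 / 1.6, 0.4 / 1.6), tolerance = 1e-10)
  # general case integrates to 1 when the denominator is far from zero
  z2 <- seq(-6, 8, length.out = 8001)
  f2 <- dratio_normal(z2, mu1 = 0.8, sigma1 = 0.5, mu2 = 2, sigma2 = 0.15,
                      rho = -0.4)
  expect_equal(sum(diff(z2) * (head(f2, -1) + tail(f2, -1)) / 2), 1,
               tolerance = 1e-4)
})

test_that("ratio-of-normals density matches simulation of the ratio", {
  set.seed(31)
  mu1 <- 1.5; s1 <- 0.3; mu2 <- 1.9; s2 <- 0.2; rho <- -0.5
  m <- 2e5
  x1 <- rnorm(m)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(m)
  r <- (mu1 + s1 * x1) / (mu2 + s2 * x2)
  z <- seq(min(r), max(r), length.out = 4001)
  f <- dratio_normal(z, mu1, s1, mu2, s2, rho)
  cdf <- c(0, cumsum(diff(z) * (head(f, -1) + tail(f, -1)) / 2))
  qs <- approx(cdf / max(cdf), z, xout = c(0.025, 0.25, 0.5, 0.75, 0.975))$y
  emp <- quantile(r, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  expect_true(all(abs(qs - emp) < 0.01))
})

test_that("quadrature marginal equals the conditional under a point time prior", {
  fx <- cached_fit()
  pat <- patient_summary(mean_foci = 2.5, sd_foci = 1.8, n_cells = 500)
  pr_point <- time_prior("uniform", 4, 4)
  dg <- dose_posterior_grid(fx$laplace, pat, pr_point)
  cond <- h2axdose:::conditional_dose_density(dg$grid, fx$laplace, pat, 4)
  cond <- cond / h2axdose:::trapz_integral(dg$grid, cond)
  expect_equal(dg$density, cond, tolerance = 1e-8)
})

test_that("simulation and quadrature give the same dose posterior", {
  fx <- cached_fit()
  pat <- generate_patient_sample(fx$params, 1.5, 2, 500, seed = 41)$summary
  pr <- time_prior("uniform", 1.5, 2.5)
  sim <- simulate_dose_posterior(fx$laplace, pat, pr, m = 1e5, seed = 42)
  grd <- dose_posterior_grid(fx$laplace, pat, pr)
  expect_lt(tv_draws_density(sim$draws, grd$grid, grd$density), 0.02)
  qs <- quantile(sim$draws, c(0.025, 0.5, 0.975), names = FALSE)
  qg <- h2axdose:::grid_quantile(grd$grid, grd$density, c(0.025, 0.5, 0.975))
  expect_true(all(abs(qs - qg) < 0.02))
})

test_that("posterior summaries behave on known shapes", {
  mk <- function(draws) structure(list(method = "simulate", draws = draws,
                                       truncate = FALSE),
                                  class = "dose_posterior")
  set.seed(51)
  u <- mk(runif(2e5))
  s <- summarize_posterior(u, 0.95)
  expect_lt(abs(s$ci_lo - 0.025), 0.005)
  expect_lt(abs(s$ci_hi - 0.975), 0.005)
  g <- mk(rnorm(2e5, 1, 0.3))
  sg <- summarize_posterior(g, 0.9)
  expect_lt(abs(sg$mean - sg$median), 0.01)
  expect_lt(abs(sg$ci_hi - sg$ci_lo - 2 * qnorm(0.95) * 0.3), 0.02)
})

test_that("a larger patient mean shifts the dose posterior stochastically upward", {
  fx <- cached_fit()
  pr <- time_prior("uniform", 3, 5)
  q_lo <- q_hi <- NULL
  for (xb in c(1.2, 2.0)) {
    pat <- patient_summary(mean_foci = xb, sd_foci = 1.5, n_cells = 500)
    dp <- simulate_dose_posterior(fx$laplace, pat, pr, m = 2e4, seed = 61)
    q <- quantile(dp$draws, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    if (is.null(q_lo)) q_lo <- q else q_hi <- q
  }
  expect_true(all(q_hi > q_lo))
})

test_that("simulation is bit-for-bit reproducible from its seed", {
  fx <- cached_fit()
  pat <- patient_summary(mean_foci = 2, sd_foci = 1.4, n_cells = 300)
  pr <- time_prior("beta", 3, 5, shape1 = 5, shape2 = 5)
  d1 <- simulate_dose_posterior(fx$laplace, pat, pr, m = 10000, seed = 71)
  d2 <- simulate_dose_posterior(fx$laplace, pat, pr, m = 10000, seed = 71)
  expect_identical(d1$draws, d2$draws)
  d3 <- simulate_dose_posterior(fx$laplace, pat, pr, m = 10000, seed = 72)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("negative doses are kept in raw draws and removable only in summaries", {
  fx <- cached_fit()
  # a barely-exposed patient: mean near the spontaneous level, few cells,
  # so an appreciable share of draws lands below zero
  pat <- patient_summary(mean_foci = 0.45, sd_foci = 1.2, n_cells = 9)
  pr <- time_prior("uniform", 3, 5)
  dp <- simulate_dose_posterior(fx$laplace, pat, pr, m = 10000, seed = 81)
  expect_gt(sum(dp$draws < 0, na.rm = TRUE), 0)
  tr <- simulate_dose_posterior(fx$laplace, pat, pr, m = 10000, seed = 81,
                                truncate = TRUE)
  expect_identical(tr$draws, dp$draws)        # raw sample untouched
  expect_gte(tr$summary$ci_lo, 0)
  expect_error(simulate_dose_posterior(fx$laplace, pat, pr, m = 500),
               "10,000")
})
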