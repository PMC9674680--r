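test_that("Perks' Dirichlet prior density has its closed form on the simplex", {
  p <- mixture_params(c(0.5, 0.5), a = c(1, 2), c_ = c(1, 1),
                      u = c(0, 0), v = c(0, 0), canonical = FALSE)
  # Dirichlet(1/2, 1/2) at (1/2, 1/2) is the Beta(1/2, 1/2) density at 1/2:
  # 1 / (pi * sqrt(x (1 - x))) = 2 / pi
  expect_equal(log_prior(p, prior_spec()), log(2 / pi))
  # outside the theta box the prior excludes the point
  wide <- mixture_params(c(0.5, 0.5), a = c(1, 2), c_ = c(1, 1),
                         u = c(0, 0), v = c(4, 0), canonical = FALSE)
  expect_identical(log_prior(wide, prior_spec(v_bounds = c(-5, 2))), -Inf)
  # inside the box, differences depend only on the weights
  p2 <- mixture_params(c(0.3, 0.7), a = c(5, 9), c_ = c(2, 0.1),
                       u = c(-1, 1), v = c(-2, 0), canonical = FALSE)
  p3 <- mixture_params(c(0.3, 0.7), a = c(1, 1.1), c_ = c(1, 1),
                       u = c(0, 0), v = c(0, 0), canonical = FALSE)
  expect_equal(log_prior(p2, prior_spec()), log_prior(p3, prior_spec()))
})

test_that("log posterior is likelihood plus prior over the free parametrization", {
  data <- tiny_data()
  spec <- mixture_spec(2, shared_u = TRUE)
  prior <- prior_spec()
  p <- random_params(2, shared_u = TRUE, seed = 31)
  free <- params_to_free(p, spec)
  expect_equal(log_posterior(free, data, prior, spec),
               log_likelihood(p, data) + log_prior(p, prior),
               tolerance = 1e-12)
  expect_error(log_posterior(rep(0, 5), data, prior, spec), "expected 8")
  # a point outside the prior box is excluded, not an exception
  bad <- free; bad["v1"] <- 3
  expect_identical(log_posterior(bad, data, prior, spec), -Inf)
})

test_that("finite-difference curvature reproduces textbook Laplace results", {
  fdh <- h2axdose:::fd_hessian
  # quadratic log-density: Laplace is exact, Sigma recovers the inverse
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  fn <- function(x) -0.5 * drop(t(x) %*% A %*% x) + sum(c(1, -2) * x)
  H <- fdh(fn, c(0.3, -0.7))
  expect_equal(solve(-H), solve(A), tolerance = 1e-6)
  # Poisson likelihood parametrized by its rate: posterior variance lambda/N
  set.seed(91)
  y <- rpois(400, 1.3)
  lhat <- mean(y)
  ll <- function(l) sum(dpois(y, l, log = TRUE))
  H1 <- fdh(ll, lhat)
  expect_equal(drop(-1 / H1), lhat / length(y), tolerance = 1e-4)
})

test_that("K = 1 MAP matches an independent single-surface MLE", {
  params <- mixture_params(1, a = 4, c_ = 0.6, u = -0.4, v = -0.7)
  data <- generate_calibration_data(params,
                                    design_grid(cells_per_condition = 200),
                                    seed = 41)
  fit <- map_fit(data, mixture_spec(1), n_starts = 3, seed = 42)
  # independent oracle: direct MLE over (a, c, u, v) on the natural scale
  df <- as.data.frame(data)
  nll <- function(th) {
    lam <- th[2] * df$time_h^th[3] + th[1] * df$time_h^th[4] * df$dose_gy
    if (any(lam <= 0)) return(1e12)
    -sum(dpois(df$foci_count, lam, log = TRUE))
  }
  mle <- optim(c(3, 0.5, -0.3, -0.5), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$params$a, mle$par[1], tolerance = 1e-3)
  expect_equal(fit$params$c, mle$par[2], tolerance = 1e-3)
  expect_equal(fit$params$u, mle$par[3], tolerance = 1e-2)
  expect_equal(fit$params$v, mle$par[4], tolerance = 1e-2)
  # and the truth is recovered within 3 posterior sds
  lap <- laplace_approx(fit, data)
  sds <- sqrt(diag(lap$cov))
  truth <- params_to_free(params, mixture_spec(1))
  expect_true(all(abs(fit$free - truth) <= 3 * sds))
})

test_that("K = 2 MAP recovers well-separated weights from large samples", {
  params <- mixture_params(c(0.6, 0.4), a = c(2, 8), c_ = c(0.3, 1),
                           u = -0.3, v = c(-0.4, -0.9))
  data <- generate_calibration_data(params,
                                    design_grid(cells_per_condition = 400),
                                    seed = 51)
  fit <- map_fit(data, mixture_spec(2, shared_u = TRUE), n_starts = 4,
                 seed = 52)
  expect_true(all(abs(fit$params$weights - params$weights) < 0.05))
  expect_gt(fit$log_posterior, max(fit$starts$log_posterior_start, na.rm = TRUE) - 1e-8)
})

test_that("single-time designs leave the time exponents unidentified and are flagged", {
  params <- mixture_params(1, a = 3, c_ = 0.5, u = -0.3, v = -0.5)
  data <- generate_calibration_data(params,
                                    design_grid(doses = c(0, 1, 2, 3),
                                                times = 2,
                                                cells_per_condition = 150),
                                    seed = 61)
  fit <- map_fit(data, mixture_spec(1), n_starts = 2, seed = 62)
  # at a single t, t^u confounds with c: curvature is singular along that
  # direction, so the Laplace step must warn or refuse
  expect_condition(laplace_approx(fit, data),
                   regexp = "ill-conditioned|negative-definite|near-singular")
})

test_that("Laplace covariance is reproducible across start orderings reaching the same mode", {
  fx <- cached_fit()
  fit2 <- map_fit(fx$data, fx$fit$spec, n_starts = 3, seed = 999)
  expect_equal(fit2$free, fx$fit$free, tolerance = 1e-3)
  lap2 <- laplace_approx(fit2, fx$data)
  expect_equal(lap2$cov, fx$laplace$cov, tolerance = 1e-2)
})

test_that("AIC model selection ranks candidates and prefers the generating K", {
  # structure of the table on one dataset
  data <- tiny_data(seed = 71, cells = 80)
  sel <- select_model(data, K_grid = 1:2, shared_u_options = TRUE,
                      n_starts = 2, seed = 72)
  expect_s3_class(sel, "model_selection")
  expect_true(all(diff(sel$aic[sel$status == "ok"]) >= 0))
  expect_identical(sel$p, vapply(seq_len(nrow(sel)), function(i)
    n_free_params(mixture_spec(sel$K[i], sel$shared_u[i])), integer(1)))
  # selection consistency: K = 2 truth beats K = 1 in >= 90% of replicates
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- generate_calibration_data(true_params(),
                                   design_grid(doses = c(0, 1, 3),
                                               times = c(0.5, 2, 24),
                                               cells_per_condition = 150),
                                   seed = 700 + r)
    s <- select_model(d, K_grid = 1:2, shared_u_options = TRUE,
                      n_starts = 2, seed = 800 + r)
    if (s$K[1] == 2L) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("the posterior sampler agrees with conjugate closed forms and the MAP", {
  # single condition at d = 0, t = 1: only the spontaneous rate c is
  # informed; flat prior on log c makes its posterior Gamma(sum y, N)
  set.seed(81)
  df <- data.frame(foci_count = rpois(200, 0.8), dose_gy = 0, time_h = 1)
  data <- as_calibration_data(df)
  mc <- suppressWarnings(mcmc_sample(data, mixture_spec(1), n_iter = 2000,
                                     seed = 82))
  c_draws <- exp(mc$draws[, "log_c1"])
  post_mean <- sum(df$foci_count) / nrow(df)        # Gamma mean = ybar
  expect_lt(abs(mean(c_draws) - post_mean), 0.04)
  expect_lt(abs(sd(c_draws) - sqrt(sum(df$foci_count)) / nrow(df)), 0.02)
  # on a surface design the posterior mean stays near the MAP mode
  data2 <- tiny_data(seed = 83, cells = 120)
  fit2 <- map_fit(data2, mixture_spec(2, shared_u = TRUE), n_starts = 3,
                  seed = 84)
  mc2 <- suppressWarnings(mcmc_sample(data2, mixture_spec(2, shared_u = TRUE),
                                      n_iter = 2000, seed = 85,
                                      init = fit2$free))
  lap2 <- laplace_approx(fit2, data2)
  sds <- sqrt(diag(lap2$cov))
  expect_true(all(abs(colMeans(mc2$draws) - fit2$free) < 4 * sds))
})
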