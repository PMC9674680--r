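# Shared fixtures. Expensive fits are built once per session and cached, so
# several test files can reuse the same calibrated model.

.fixtures <- new.env(parent = emptyenv())

# K = 2 truth used throughout: realistic foci magnitudes (see
# example_mixture_params)
true_params <- function() example_mixture_params()

# moderate-size synthetic calibration experiment + MAP + Laplace (one fit)
cached_fit <- function() {
  if (is.null(.fixtures$fit)) {
    params <- true_params()
    data <- generate_calibration_data(params, design_grid(), seed = 421)
    fit <- map_fit(data, mixture_spec(2, shared_u = TRUE), n_starts = 4,
                   seed = 422)
    laplace <- laplace_approx(fit, data)
    .fixtures$fit <- list(params = params, data = data, fit = fit,
                          laplace = laplace)
  }
  .fixtures$fit
}

# small dataset for cheap likelihood / IO tests
tiny_data <- function(seed = 7, cells = 40) {
  generate_calibration_data(true_params(),
                            design_grid(doses = c(0, 1, 3),
                                        times = c(0.5, 2, 24),
                                        cells_per_condition = cells),
                            seed = seed)
}

# parameters with K components and distinct coefficients, for property tests
random_params <- function(K, shared_u = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rgamma(K, 2); w <- w / sum(w)
  mixture_params(w,
                 a = sort(stats::runif(K, 0.5, 8)),
                 c_ = stats::runif(K, 0.1, 1.5),
                 u = if (shared_u) stats::runif(1, -1, 0) else
                   stats::runif(K, -1, 0),
                 v = stats::runif(K, -1.2, -0.1))
}

# total-variation distance between dose draws and a (grid, density) pair,
# computed on a common binning
tv_draws_density <- function(draws, grid, density, n_bins = 80) {
  draws <- draws[is.finite(draws)]
  lo <- min(grid); hi <- max(grid)
  draws <- pmin(pmax(draws, lo), hi)
  br <- seq(lo, hi, length.out = n_bins + 1)
  p_emp <- as.numeric(table(cut(draws, br, include.lowest = TRUE))) / length(draws)
  cdf <- function(x) {
    # trapezoid CDF of the density at x
    vapply(x, function(xx) {
      keep <- grid <= xx
      if (sum(keep) < 2) return(0)
      sum(diff(grid[keep]) * (head(density[keep], -1) + tail(density[keep], -1)) / 2)
    }, numeric(1))
  }
  cp <- cdf(br)
  cp <- cp / cp[length(cp)]
  p_grid <- diff(cp)
  0.5 * sum(abs(p_emp - p_grid))
}
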