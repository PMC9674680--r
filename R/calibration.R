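#' Prior specification for the mixture posterior
#'
#' Perks' symmetric Dirichlet prior (concentration 1/K, resolved at use time
#' when \code{dirichlet_concentration} is NULL) on the weights, and independent
#' uniform priors on the surface coefficients, expressed as a box in the free
#' parametrization (log a, log c, u, v). The default box is generous for
#' gamma-H2AX kinetics: at most a few tens of foci per cell and decay over a
#' 24 h window.
#'
#' @param dirichlet_concentration per-component Dirichlet concentration, or
#'   NULL for Perks' 1/K.
#' @param log_a_bounds,log_c_bounds,u_bounds,v_bounds length-2 (lower, upper)
#'   uniform-prior supports.
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(dirichlet_concentration = NULL,
                       log_a_bounds = c(-10, 5), log_c_bounds = c(-10, 5),
                       u_bounds = c(-5, 2), v_bounds = c(-5, 2)) {
  chk <- function(b) stopifnot(length(b) == 2L, b[1] < b[2])
  chk(log_a_bounds); chk(log_c_bounds); chk(u_bounds); chk(v_bounds)
  if (!is.null(dirichlet_concentration))
    stopifnot(dirichlet_concentration > 0)
  structure(list(dirichlet_concentration = dirichlet_concentration,
                 log_a_bounds = log_a_bounds, log_c_bounds = log_c_bounds,
                 u_bounds = u_bounds, v_bounds = v_bounds),
            class = "prior_spec")
}

perks_concentration <- function(prior, K) {
  if (is.null(prior$dirichlet_concentration)) 1 / K
  else prior$dirichlet_concentration
}

# lower/upper bound vectors over the free coordinates (weights unbounded;
# clamped to a wide box for L-BFGS-B)
free_bounds <- function(spec, prior, alr_limit = 15) {
  K <- spec$K
  nu <- if (spec$shared_u) 1L else K
  lower <- c(rep(-alr_limit, K - 1L), rep(prior$log_a_bounds[1], K),
             rep(prior$log_c_bounds[1], K), rep(prior$u_bounds[1], nu),
             rep(prior$v_bounds[1], K))
  upper <- c(rep(alr_limit, K - 1L), rep(prior$log_a_bounds[2], K),
             rep(prior$log_c_bounds[2], K), rep(prior$u_bounds[2], nu),
             rep(prior$v_bounds[2], K))
  list(lower = lower, upper = upper)
}

in_theta_box <- function(params, prior) {
  all(log(params$a) >= prior$log_a_bounds[1], log(params$a) <= prior$log_a_bounds[2],
      log(params$c) >= prior$log_c_bounds[1], log(params$c) <= prior$log_c_bounds[2],
      params$u >= prior$u_bounds[1], params$u <= prior$u_bounds[2],
      params$v >= prior$v_bounds[1], params$v <= prior$v_bounds[2])
}

#' Log prior density
#'
#' Dirichlet (Perks) log density at the weights plus the flat contribution of
#' the uniform box on the surface coefficients; \code{-Inf} outside the box.
#' The uniform normalizing constant is omitted (it cancels in the posterior).
#'
#' @param params a \code{\link{mixture_params}}.
#' @param prior a \code{\link{prior_spec}}.
#' @return log density up to an additive constant; \code{-Inf} when excluded.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  if (!in_theta_box(params, prior)) return(-Inf)
  K <- params$K
  conc <- perks_concentration(prior, K)
  lgamma(K * conc) - K * lgamma(conc) + sum((conc - 1) * log(params$weights))
}

#' Unnormalized log posterior over the free parametrization
#'
#' \code{log_likelihood + log_prior} evaluated at the natural parameters that
#' the free vector maps to. Invalid points (outside the prior box, or with a
#' non-positive component mean) return \code{-Inf}.
#'
#' @param free free-parameter vector of length \code{n_free_params(spec)}.
#' @param data a \code{calib_data}.
#' @param prior a \code{\link{prior_spec}}.
#' @param spec a \code{\link{mixture_spec}}.
#' @return log posterior up to the normalizing constant.
#' @export
log_posterior <- function(free, data, prior, spec) {
  params <- free_to_params(free, spec)
  lp <- log_prior(params, prior)
  if (!is.finite(lp)) return(-Inf)
  ll <- log_likelihood(params, data)
  if (!is.finite(ll)) return(-Inf)
  ll + lp
}

# crude single-surface start: least squares of condition means on
# m(d,t) ~ c t^u + a t^v d over (log c, u, log a, v)
moment_start <- function(data) {
  cond <- attr(data, "conditions")
  ytab <- attr(data, "ytab")
  mbar <- vapply(cond$key, function(k) {
    yt <- ytab[[k]]; sum(yt$foci_count * yt$n_cells) / sum(yt$n_cells)
  }, numeric(1))
  d <- cond$dose_gy; t <- cond$time_h
  m0 <- mbar[d == 0]
  c0 <- if (length(m0)) max(mean(m0), 0.05) else max(min(mbar), 0.05)
  pos <- d > 0
  a0 <- if (any(pos)) max(mean((mbar[pos] - c0) / d[pos]), 0.05) else 1
  obj <- function(th) {
    fit <- exp(th[1]) * t^th[2] + exp(th[3]) * t^th[4] * d
    sum((mbar - fit)^2)
  }
  op <- stats::optim(c(log(c0), -0.3, log(a0), -0.5), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
  list(log_c = op$par[1], u = op$par[2], log_a = op$par[3], v = op$par[4])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo + 1e-6), hi - 1e-6)

#' Maximum a posteriori fit of the mixture surface model
#'
#' Multi-start box-constrained quasi-Newton (L-BFGS-B) maximization of
#' \code{\link{log_posterior}} over the free parametrization. The first start
#' is a deterministic single-surface moment fit replicated across components;
#' the remaining starts jitter the component coefficients by up to roughly
#' +/-50\% and draw weights from a flat Dirichlet. The best local optimum is
#' returned with components in canonical order.
#'
#' @param data a \code{calib_data}.
#' @param spec a \code{\link{mixture_spec}}.
#' @param prior a \code{\link{prior_spec}}.
#' @param n_starts number of optimization starts (>= 1).
#' @param seed integer seed making the start set reproducible, or NULL.
#' @return an object of class \code{map_fit}: fitted \code{params}, the
#'   \code{free} vector, \code{log_posterior}, \code{log_lik}, \code{aic},
#'   and a per-start diagnostics table.
#' @export
map_fit <- function(data, spec, prior = prior_spec(), n_starts = 10,
                    seed = NULL) {
  stopifnot(inherits(data, "calib_data"), inherits(spec, "mixture_spec"),
            n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K
  ms <- moment_start(data)
  bnd <- free_bounds(spec, prior)
  nu <- if (spec$shared_u) 1L else K

  make_start <- function(jitter) {
    if (!jitter) {
      # split the single surface into K nearby components
      off <- if (K > 1L) seq(-0.2, 0.2, length.out = K) else 0
      w <- rep(1 / K, K)
      la <- ms$log_a + off; lc <- ms$log_c + off
      u <- rep(ms$u, nu); v <- rep(ms$v, K)
    } else {
      w <- stats::rgamma(K, 1); w <- w / sum(w)
      la <- ms$log_a + stats::runif(K, -0.7, 0.7)
      lc <- ms$log_c + stats::runif(K, -0.7, 0.7)
      u <- rep(ms$u, nu) + stats::runif(nu, -0.4, 0.4)
      v <- rep(ms$v, K) + stats::runif(K, -0.4, 0.4)
    }
    z <- if (K > 1L) log(w[-K] / w[K]) else numeric(0)
    free <- c(z, la, lc, u, v)
    clamp(free, bnd$lower, bnd$upper)
  }

  neg <- function(f) {
    lp <- log_posterior(f, data, prior, spec)
    if (!is.finite(lp)) 1e15 else -lp
  }

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    st <- make_start(jitter = s > 1L)
    res <- tryCatch(
      stats::optim(st, neg, method = "L-BFGS-B",
                   lower = bnd$lower, upper = bnd$upper,
                   control = list(maxit = 500, factr = 1e6)),
      error = function(e) e)
    runs[[s]] <- if (inherits(res, "error"))
      list(ok = FALSE, msg = conditionMessage(res), lp0 = -neg(st))
    else list(ok = TRUE, par = res$par, lp = -res$value, lp0 = -neg(st),
              convergence = res$convergence)
  }
  ok <- vapply(runs, function(r) isTRUE(r$ok) && is.finite(r$lp), logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(r) r$msg %||% "non-finite optimum", character(1))
    stop("no optimization start converged: ", paste(unique(msgs), collapse = "; "))
  }
  best <- runs[[which.max(ifelse(ok, vapply(runs, function(r)
    if (isTRUE(r$ok)) r$lp else -Inf, numeric(1)), -Inf))]]
  params <- canonical_order(free_to_params(best$par, spec))
  free <- params_to_free(params, spec)
  lp <- log_posterior(free, data, prior, spec)
  ll <- log_likelihood(params, data)
  diag_tab <- data.frame(
    start = seq_len(n_starts),
    converged = vapply(runs, function(r) isTRUE(r$ok) &&
                         identical(r$convergence, 0L), logical(1)),
    log_posterior = vapply(runs, function(r)
      if (isTRUE(r$ok)) r$lp else NA_real_, numeric(1)),
    log_posterior_start = vapply(runs, function(r) r$lp0, numeric(1)))
  structure(list(params = params, free = free, spec = spec, prior = prior,
                 log_posterior = lp, log_lik = ll,
                 aic = 2 * n_free_params(spec) - 2 * ll,
                 n_obs = attr(data, "N"), starts = diag_tab, seed = seed),
            class = "map_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit: K = %d%s, p = %d, N = %d cells\n", x$spec$K,
              if (x$spec$shared_u) " (shared u)" else "",
              n_free_params(x$spec), x$n_obs))
  cat(sprintf("  log posterior = %.3f, log lik = %.3f, AIC = %.2f\n",
              x$log_posterior, x$log_lik, x$aic))
  print(x$params)
  invisible(x)
}

# central finite-difference Hessian, step 1e-4 * (1 + |x_j|), symmetrized
fd_hessian <- function(fn, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * (1 + abs(x))
  f0 <- fn(x)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    ej <- rep(0, p); ej[j] <- h[j]
    H[j, j] <- (fn(x + ej) - 2 * f0 + fn(x - ej)) / h[j]^2
    if (j < p) for (k in (j + 1L):p) {
      ek <- rep(0, p); ek[k] <- h[k]
      H[j, k] <- (fn(x + ej + ek) - fn(x + ej - ek) -
                    fn(x - ej + ek) + fn(x - ej - ek)) / (4 * h[j] * h[k])
      H[k, j] <- H[j, k]
    }
  }
  (H + t(H)) / 2
}

#' Laplace (Gaussian) approximation of the mixture posterior
#'
#' Approximates the posterior by \eqn{N_p(\phi^*, \hat\Sigma)} with
#' \eqn{\hat\Sigma} the inverse of the negative Hessian of the log posterior
#' at the mode, computed by central finite differences in the free
#' parametrization. Slightly non-positive curvature eigenvalues (numerical
#' noise at a flat mode) are jittered to a small positive floor with a
#' warning; genuinely indefinite Hessians are an error naming the offending
#' eigendirections.
#'
#' @param fit a \code{\link{map_fit}}.
#' @param data the \code{calib_data} used for the fit.
#' @param prior,spec prior and specification; default to those of the fit.
#' @return an object of class \code{laplace_posterior} with elements
#'   \code{mode} (free vector), \code{params}, \code{cov} (p x p),
#'   \code{parametrization} (coordinate names), \code{log_posterior_at_mode},
#'   \code{condition_number}, \code{jittered}.
#' @export
laplace_approx <- function(fit, data, prior = fit$prior, spec = fit$spec) {
  stopifnot(inherits(fit, "map_fit"))
  fn <- function(f) log_posterior(f, data, prior, spec)
  H <- fd_hessian(fn, fit$free)
  negH <- -(H + t(H)) / 2
  eg <- eigen(negH, symmetric = TRUE)
  vals <- eg$values
  nm <- free_names(spec)
  jittered <- FALSE
  if (any(vals <= 0)) {
    if (min(vals) > -1e-6 * max(vals)) {
      vals <- pmax(vals, 1e-8 * max(vals))
      jittered <- TRUE
      warning("near-singular curvature at the mode; covariance jittered")
    } else {
      bad <- which(vals <= 0)
      dirs <- vapply(bad, function(b) nm[which.max(abs(eg$vectors[, b]))],
                     character(1))
      stop("Hessian not negative-definite at the mode; offending directions ",
           "load on: ", paste(unique(dirs), collapse = ", "))
    }
  }
  Sigma <- eg$vectors %*% (t(eg$vectors) / vals)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(nm, nm)
  kappa <- max(vals) / min(vals)
  if (kappa > 1e8)
    warning(sprintf("ill-conditioned Hessian at the mode (condition number %.2e); some parameters are weakly identified", kappa))
  structure(list(mode = stats::setNames(fit$free, nm), params = fit$params,
                 cov = Sigma, spec = spec, parametrization = nm,
                 log_posterior_at_mode = fit$log_posterior,
                 aic = fit$aic, condition_number = kappa, jittered = jittered),
            class = "laplace_posterior")
}

#' @export
print.laplace_posterior <- function(x, ...) {
  p <- length(x$mode)
  cat(sprintf("Laplace posterior: K = %d%s, p = %d (%d unique covariance entries)\n",
              x$spec$K, if (x$spec$shared_u) " (shared u)" else "", p,
              p * (p + 1) / 2))
  cat(sprintf("  log posterior at mode = %.3f, condition number = %.2e\n",
              x$log_posterior_at_mode, x$condition_number))
  invisible(x)
}

#' AIC-based model selection over mixture specifications
#'
#' Fits every candidate (K, shared_u) combination by \code{\link{map_fit}} and
#' ranks by AIC. Individual fit failures are recorded in the table, not fatal.
#'
#' @param data a \code{calib_data}.
#' @param K_grid integer vector of component counts to try.
#' @param shared_u_options logical vector of exponent-sharing options.
#' @param prior a \code{\link{prior_spec}}.
#' @param n_starts starts per candidate fit.
#' @param seed integer seed, or NULL.
#' @return a data frame of class \code{model_selection}, sorted by AIC
#'   ascending (winner first), with the fitted objects in
#'   \code{attr(, "fits")}.
#' @export
select_model <- function(data, K_grid = 2:5, shared_u_options = c(TRUE, FALSE),
                         prior = prior_spec(), n_starts = 10, seed = NULL) {
  stopifnot(length(K_grid) >= 1)
  grid <- expand.grid(K = as.integer(K_grid), shared_u = shared_u_options)
  grid <- grid[!(grid$K == 1L & !grid$shared_u), , drop = FALSE]  # identical models
  if (!is.null(seed)) seeds <- seed + seq_len(nrow(grid)) else
    seeds <- rep(list(NULL), nrow(grid))
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- mixture_spec(grid$K[i], grid$shared_u[i])
    f <- tryCatch(map_fit(data, sp, prior, n_starts = n_starts,
                          seed = if (is.list(seeds)) NULL else seeds[i]),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(K = sp$K, shared_u = sp$shared_u,
                              p = n_free_params(sp), log_posterior = NA_real_,
                              log_lik = NA_real_, aic = NA_real_,
                              status = conditionMessage(f))
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(K = sp$K, shared_u = sp$shared_u,
                              p = n_free_params(sp),
                              log_posterior = f$log_posterior,
                              log_lik = f$log_lik, aic = f$aic, status = "ok")
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(ifelse(is.na(tab$aic), Inf, tab$aic))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("model_selection", "data.frame"))
}

#' Best fit from a model-selection table
#' @param selection a \code{\link{select_model}} result.
#' @return the winning \code{\link{map_fit}}.
#' @export
selected_fit <- function(selection) {
  fits <- attr(selection, "fits")
  if (is.null(fits[[1]])) stop("no successful fit in selection table")
  fits[[1]]
}

#' Adaptive random-walk Metropolis-within-Gibbs posterior sampler
#'
#' Coordinate-wise Gaussian random-walk sampler over the free parametrization,
#' with per-coordinate proposal scales adapted during burn-in toward an
#' acceptance rate of about 0.44. Intended as an independent cross-check of
#' the Laplace approximation (the surface has no conjugate structure, so a
#' pure Gibbs sampler is not available). Retained draws are relabeled to
#' canonical component order.
#'
#' @param data a \code{calib_data}.
#' @param spec a \code{\link{mixture_spec}}.
#' @param prior a \code{\link{prior_spec}}.
#' @param n_iter total iterations (>= 1000); the first half is burn-in.
#' @param seed integer seed, or NULL.
#' @param init free-vector start, e.g. a MAP mode (defaults to a moment start).
#' @return an object of class \code{mcmc_posterior}: \code{draws} (kept
#'   iterations x p, free scale, canonically relabeled), acceptance rates and
#'   the spec. Warns when the post-adaptation acceptance rate leaves
#'   (0.05, 0.7).
#' @export
mcmc_sample <- function(data, spec, prior = prior_spec(), n_iter = 5000,
                        seed = NULL, init = NULL) {
  stopifnot(n_iter >= 1000)
  if (!is.null(seed)) set.seed(seed)
  p <- n_free_params(spec)
  if (is.null(init)) {
    fit0 <- map_fit(data, spec, prior, n_starts = 3)
    init <- fit0$free
  }
  stopifnot(length(init) == p)
  bnd <- free_bounds(spec, prior)
  cur <- clamp(as.numeric(init), bnd$lower, bnd$upper)
  lp_cur <- log_posterior(cur, data, prior, spec)
  if (!is.finite(lp_cur)) stop("initial point has zero posterior density")
  burn <- floor(n_iter / 2)
  scales <- rep(0.05, p)
  acc <- att <- rep(0, p)
  acc_post <- att_post <- rep(0, p)
  kept <- matrix(NA_real_, n_iter - burn, p)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- cur
      prop[j] <- cur[j] + stats::rnorm(1, 0, scales[j])
      lp_prop <- log_posterior(prop, data, prior, spec)
      att[j] <- att[j] + 1
      accept <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
      if (accept) { cur <- prop; lp_cur <- lp_prop; acc[j] <- acc[j] + 1 }
      if (it > burn) {
        att_post[j] <- att_post[j] + 1
        if (accept) acc_post[j] <- acc_post[j] + 1
      }
    }
    if (it <= burn && it %% 50 == 0) {
      rate <- ifelse(att > 0, acc / att, 0.44)
      scales <- scales * exp(0.6 * (rate - 0.44))
      acc[] <- 0; att[] <- 0
    }
    if (it > burn) kept[it - burn, ] <- cur
  }
  # relabel each draw to canonical component order
  for (i in seq_len(nrow(kept)))
    kept[i, ] <- params_to_free(canonical_order(
      free_to_params(kept[i, ], spec)), spec)
  colnames(kept) <- free_names(spec)
  rate_post <- mean(acc_post / pmax(att_post, 1))
  if (rate_post < 0.05 || rate_post > 0.7)
    warning(sprintf("post-adaptation acceptance rate %.3f outside (0.05, 0.7)",
                    rate_post))
  structure(list(draws = kept, spec = spec, prior = prior,
                 acceptance_rate = rate_post, n_iter = n_iter, burn_in = burn,
                 seed = seed),
            class = "mcmc_posterior")
}

#' @export
print.mcmc_posterior <- function(x, ...) {
  cat(sprintf("MCMC posterior: %d kept draws (of %d iterations), acceptance %.2f\n",
              nrow(x$draws), x$n_iter, x$acceptance_rate))
  invisible(x)
}
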