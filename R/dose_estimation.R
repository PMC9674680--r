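#' Prior on the time since exposure
#'
#' Either uniform on (t_lo, t_hi) or a scaled symmetric/asymmetric beta:
#' \eqn{t = t_{lo} + (t_{hi} - t_{lo}) B}, \eqn{B \sim Beta(\alpha, \beta)}.
#'
#' @param family "uniform" or "beta".
#' @param t_lo,t_hi interval endpoints in hours, 0 < t_lo <= t_hi (equal
#'   endpoints give a point prior, useful for fixed-time estimation).
#' @param shape1,shape2 beta shapes (> 0), required for family "beta".
#' @return an object of class \code{time_prior}.
#' @export
time_prior <- function(family = c("uniform", "beta"), t_lo, t_hi,
                       shape1 = NULL, shape2 = NULL) {
  family <- match.arg(family)
  stopifnot(t_lo > 0, t_hi >= t_lo)
  if (family == "beta") {
    stopifnot(!is.null(shape1), !is.null(shape2), shape1 > 0, shape2 > 0)
    if (t_hi == t_lo) stop("beta prior needs t_lo < t_hi")
  }
  structure(list(family = family, t_lo = t_lo, t_hi = t_hi,
                 shape1 = shape1, shape2 = shape2), class = "time_prior")
}

#' @export
print.time_prior <- function(x, ...) {
  if (x$t_lo == x$t_hi)
    cat(sprintf("Time prior: point mass at %g h\n", x$t_lo))
  else if (x$family == "uniform")
    cat(sprintf("Time prior: uniform on (%g, %g) h\n", x$t_lo, x$t_hi))
  else
    cat(sprintf("Time prior: Beta(%g, %g) scaled to (%g, %g) h\n",
                x$shape1, x$shape2, x$t_lo, x$t_hi))
  invisible(x)
}

#' Time-prior density
#' @param prior a \code{\link{time_prior}}.
#' @param t times in hours.
#' @return density values (integrating to 1 over the support).
#' @export
dtime_prior <- function(prior, t) {
  w <- prior$t_hi - prior$t_lo
  if (w == 0) stop("point prior has no density")
  inside <- t >= prior$t_lo & t <= prior$t_hi
  dens <- numeric(length(t))
  if (prior$family == "uniform") dens[inside] <- 1 / w
  else dens[inside] <- stats::dbeta((t[inside] - prior$t_lo) / w,
                                    prior$shape1, prior$shape2) / w
  dens
}

#' Draw times from the prior
#' @param prior a \code{\link{time_prior}}.
#' @param m number of draws.
#' @param seed integer seed, or NULL.
#' @return numeric vector of m times in (t_lo, t_hi).
#' @export
sample_time_prior <- function(prior, m, seed = NULL) {
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- prior$t_hi - prior$t_lo
  if (w == 0) return(rep(prior$t_lo, m))
  if (prior$family == "uniform") stats::runif(m, prior$t_lo, prior$t_hi)
  else prior$t_lo + w * stats::rbeta(m, prior$shape1, prior$shape2)
}

#' Aggregate summary of a patient's foci counts
#'
#' The estimating laboratory receives only the mean foci count per cell, its
#' sample standard deviation (or standard error) and the number of cells
#' scored; the patient's expected count is modeled as
#' \eqn{\mu \sim N(\bar x, s^2/n)}.
#'
#' @param mean_foci sample mean foci per cell (>= 0).
#' @param sd_foci sample standard deviation s (provide this or se_foci).
#' @param se_foci standard error of the mean, \eqn{s/\sqrt{n}}.
#' @param n_cells number of cells scored (>= 2).
#' @return an object of class \code{patient_summary}.
#' @export
patient_summary <- function(mean_foci, sd_foci = NULL, se_foci = NULL,
                            n_cells) {
  stopifnot(mean_foci >= 0, n_cells >= 2)
  if (is.null(sd_foci) == is.null(se_foci))
    stop("provide exactly one of sd_foci or se_foci")
  if (is.null(sd_foci)) sd_foci <- se_foci * sqrt(n_cells)
  stopifnot(sd_foci >= 0)
  structure(list(mean = mean_foci, sd = sd_foci, n = as.integer(n_cells),
                 se = sd_foci / sqrt(n_cells)), class = "patient_summary")
}

#' Dose implied by an expected count at a known time
#'
#' Inverts the calibration line: \eqn{d = (\mu - \alpha_t) / \beta_t}. The
#' value may be negative when \eqn{\mu < \alpha_t}; raw draws are not
#' truncated (truncation is a reporting choice, see
#' \code{\link{summarize_posterior}}).
#'
#' @param mu expected foci count.
#' @param alpha,beta calibration-line intercept and slope at the time of
#'   interest.
#' @return dose in Gy (possibly negative).
#' @export
dose_given_t <- function(mu, alpha, beta) {
  if (any(beta == 0)) stop("division by zero: beta_t = 0")
  (mu - alpha) / beta
}

# vectorized per-draw (alpha, beta) sampling: mean + chol factor per time
draw_alpha_beta <- function(laplace, tstar) {
  m <- length(tstar)
  ab <- alpha_beta_point(laplace$params, tstar)      # m x 2 means
  p <- length(laplace$mode)
  # build m x p Jacobian rows for alpha and beta as functions of t
  G1 <- matrix(0, m, p); G2 <- matrix(0, m, p)
  params <- laplace$params; spec <- laplace$spec
  K <- spec$K
  u <- if (spec$shared_u) rep(params$u, K) else params$u
  w <- params$weights
  lt <- log(tstar)
  cc <- exp(outer(lt, u)) * rep(params$c, each = m)  # m x K: c_k t^u_k
  ca <- exp(outer(lt, params$v)) * rep(params$a, each = m)
  alpha <- drop(cc %*% w); beta <- drop(ca %*% w)
  i <- 0L
  if (K > 1L) {
    for (j in seq_len(K - 1L)) {
      G1[, j] <- w[j] * (cc[, j] - alpha)
      G2[, j] <- w[j] * (ca[, j] - beta)
    }
    i <- K - 1L
  }
  G2[, i + seq_len(K)] <- sweep(ca, 2, w, `*`)
  i <- i + K
  G1[, i + seq_len(K)] <- sweep(cc, 2, w, `*`)
  i <- i + K
  if (spec$shared_u) {
    G1[, i + 1L] <- alpha * lt
    i <- i + 1L
  } else {
    G1[, i + seq_len(K)] <- sweep(cc, 2, w, `*`) * lt
    i <- i + K
  }
  G2[, i + seq_len(K)] <- sweep(ca, 2, w, `*`) * lt
  S <- laplace$cov
  v11 <- rowSums((G1 %*% S) * G1)
  v22 <- rowSums((G2 %*% S) * G2)
  v12 <- rowSums((G1 %*% S) * G2)
  v11 <- pmax(v11, 0); v22 <- pmax(v22, 0)
  # per-row Cholesky of the 2x2 covariance
  L11 <- sqrt(v11)
  L21 <- ifelse(L11 > 0, v12 / L11, 0)
  L22 <- sqrt(pmax(v22 - L21^2, 0))
  z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
  cbind(alpha = ab[, 1] + L11 * z1,
        beta = ab[, 2] + L21 * z1 + L22 * z2)
}

#' Monte-Carlo dose posterior under time-since-exposure uncertainty
#'
#' The simulation algorithm: repeat m times (m >= 10,000) — (1) draw a time
#' t* from the prior; (2) draw (alpha, beta) from the posterior of the
#' calibration line at t* (delta-method bivariate normal for a Laplace
#' posterior; a resampled posterior draw for an MCMC posterior); (3) draw the
#' patient's expected count \eqn{\mu^* \sim N(\bar x, s^2/n)}; (4) record
#' \eqn{d^* = (\mu^* - \alpha)/\beta}. The recorded doses are draws from the
#' marginal posterior \eqn{\pi(d \mid y, x)}.
#'
#' @param posterior a \code{laplace_posterior} or \code{mcmc_posterior}.
#' @param patient a \code{\link{patient_summary}}.
#' @param prior a \code{\link{time_prior}}.
#' @param m number of simulation draws (>= 10,000 unless
#'   \code{enforce_floor = FALSE}, used only in cheap internal checks).
#' @param seed integer seed, or NULL.
#' @param level credibility level for the attached summaries.
#' @param truncate drop negative doses in the summaries (raw draws keep them)?
#' @param enforce_floor require m >= 10,000?
#' @return an object of class \code{dose_posterior} with \code{draws} and
#'   summaries. Warns when more than 1\% of draws are invalid (beta <= 0 or
#'   non-finite).
#' @export
simulate_dose_posterior <- function(posterior, patient, prior, m = 10000,
                                    seed = NULL, level = 0.95,
                                    truncate = FALSE, enforce_floor = TRUE) {
  stopifnot(inherits(patient, "patient_summary"), inherits(prior, "time_prior"))
  if (enforce_floor && m < 10000) stop("use at least 10,000 simulation draws")
  if (!is.null(seed)) set.seed(seed)
  tstar <- sample_time_prior(prior, m)
  if (inherits(posterior, "laplace_posterior")) {
    ab <- draw_alpha_beta(posterior, tstar)
  } else if (inherits(posterior, "mcmc_posterior")) {
    idx <- sample.int(nrow(posterior$draws), m, replace = TRUE)
    spec <- posterior$spec
    nat <- lapply(seq_len(nrow(posterior$draws)), function(i)
      free_to_params(posterior$draws[i, ], spec))
    pull <- function(field, len) {
      x <- vapply(nat, `[[`, numeric(len), field)
      (if (len == 1L) matrix(x, ncol = 1L) else t(x))[idx, , drop = FALSE]
    }
    W <- pull("weights", spec$K)
    A <- pull("a", spec$K)
    C <- pull("c", spec$K)
    U <- pull("u", if (spec$shared_u) 1L else spec$K)
    if (spec$shared_u) U <- matrix(U, m, spec$K)
    V <- pull("v", spec$K)
    lt <- log(tstar)
    ab <- cbind(alpha = rowSums(W * C * exp(U * lt)),
                beta = rowSums(W * A * exp(V * lt)))
  } else stop("posterior must be a laplace_posterior or mcmc_posterior")
  mu <- stats::rnorm(m, patient$mean, patient$se)
  bad <- !is.finite(ab[, 2]) | ab[, 2] <= 0 | !is.finite(ab[, 1])
  d <- rep(NA_real_, m)
  d[!bad] <- (mu[!bad] - ab[!bad, 1]) / ab[!bad, 2]
  if (sum(bad) > 0.01 * m)
    warning(sprintf("%d of %d draws invalid (beta <= 0 or non-finite)",
                    sum(bad), m))
  out <- structure(list(method = "simulate", draws = d, m = m, seed = seed,
                        level = level, truncate = truncate,
                        n_invalid = sum(bad), time_prior = prior,
                        patient = patient),
                   class = "dose_posterior")
  out$summary <- summarize_posterior(out, level)
  out
}

#' Exact density of a ratio of correlated normals
#'
#' Density of Z = X / Y where (X, Y) is bivariate normal with means mu1, mu2,
#' standard deviations sigma1, sigma2 and correlation rho (Hinkley's formula).
#' Degenerate denominators (sigma2 ~ 0) reduce to the normal density of
#' X / mu2.
#'
#' @param z evaluation points.
#' @param mu1,sigma1 numerator mean and sd.
#' @param mu2,sigma2 denominator mean and sd.
#' @param rho correlation in (-1, 1).
#' @return density values at \code{z}.
#' @export
dratio_normal <- function(z, mu1, sigma1, mu2, sigma2, rho = 0) {
  stopifnot(sigma1 >= 0, sigma2 >= 0, abs(rho) < 1 + 1e-12)
  if (sigma1 == 0 && sigma2 == 0) stop("degenerate ratio: both sds are zero")
  if (sigma2 <= 1e-12 * (abs(mu2) + sigma1)) {
    if (mu2 == 0) stop("denominator is a point mass at zero")
    return(stats::dnorm(z, mu1 / mu2, sigma1 / abs(mu2)))
  }
  if (sigma1 == 0) sigma1 <- 1e-12 * (abs(mu1) + sigma2)  # numerical floor
  rho <- max(min(rho, 1 - 1e-10), -1 + 1e-10)
  r2 <- 1 - rho^2
  a <- sqrt(z^2 / sigma1^2 - 2 * rho * z / (sigma1 * sigma2) + 1 / sigma2^2)
  b <- mu1 * z / sigma1^2 - rho * (mu1 + mu2 * z) / (sigma1 * sigma2) +
    mu2 / sigma2^2
  cc <- mu1^2 / sigma1^2 - 2 * rho * mu1 * mu2 / (sigma1 * sigma2) +
    mu2^2 / sigma2^2
  dd <- exp((b^2 - cc * a^2) / (2 * r2 * a^2))
  term1 <- b * dd / (sqrt(2 * pi) * sigma1 * sigma2 * a^3) *
    (stats::pnorm(b / (sqrt(r2) * a)) - stats::pnorm(-b / (sqrt(r2) * a)))
  term2 <- sqrt(r2) / (pi * sigma1 * sigma2 * a^2) * exp(-cc / (2 * r2))
  pmax(term1 + term2, 0)
}

# conditional dose density pi(d | t): exact ratio of correlated normals with
# the patient's sampling variance folded into the numerator
conditional_dose_density <- function(d, laplace, patient, t) {
  abp <- alpha_beta_posterior(laplace, t)
  mu1 <- patient$mean - abp$mean[["alpha"]]
  s1 <- sqrt(patient$se^2 + abp$cov[1, 1])
  mu2 <- abp$mean[["beta"]]
  s2 <- sqrt(abp$cov[2, 2])
  rho <- if (s1 > 0 && s2 > 0) -abp$cov[1, 2] / (s1 * s2) else 0
  dratio_normal(d, mu1, s1, mu2, s2, rho)
}

#' Dose posterior by numerical integration over the time prior
#'
#' Marginalizes the joint posterior \eqn{\pi(d, t \mid y, x) =
#' \pi(d \mid t, y, x)\,\pi(t)} over t by Gauss-Legendre quadrature. The
#' conditional \eqn{\pi(d \mid t, y, x)} is the exact density of
#' \eqn{(\mu - \alpha_t)/\beta_t} — a ratio of correlated normals, with the
#' patient's sampling variance \eqn{s^2/n} folded into the numerator and the
#' correlation induced by \eqn{cov(\alpha_t, \beta_t)}.
#'
#' @param laplace a \code{laplace_posterior}.
#' @param patient a \code{\link{patient_summary}}.
#' @param prior a \code{\link{time_prior}}.
#' @param d_grid strictly increasing dose grid, or NULL for an automatic grid
#'   spanning the conditional means +/- 10 conditional sds.
#' @param n_t_nodes Gauss-Legendre node count over the prior support.
#' @param level credibility level for the attached summaries.
#' @param truncate restrict the reported density and summaries to d >= 0?
#' @return an object of class \code{dose_posterior} with \code{grid},
#'   \code{density} (normalized on the grid) and summaries. Errors when the
#'   pre-normalization mass on the grid deviates from 1 by more than 1\%
#'   (grid too narrow).
#' @export
dose_posterior_grid <- function(laplace, patient, prior, d_grid = NULL,
                                n_t_nodes = 64, level = 0.95,
                                truncate = FALSE) {
  stopifnot(inherits(laplace, "laplace_posterior"),
            inherits(patient, "patient_summary"), inherits(prior, "time_prior"))
  if (prior$t_lo == prior$t_hi) {
    nodes <- prior$t_lo; wts <- 1
  } else {
    gl <- pracma::gaussLegendre(n_t_nodes, prior$t_lo, prior$t_hi)
    nodes <- gl$x
    wts <- gl$w * dtime_prior(prior, gl$x)
    wts <- wts / sum(wts)   # quadrature discretization of the prior
  }
  if (is.null(d_grid)) {
    stats_t <- vapply(nodes, function(t) {
      abp <- alpha_beta_posterior(laplace, t)
      mu <- (patient$mean - abp$mean[["alpha"]]) / abp$mean[["beta"]]
      sdv <- sqrt(pmax(patient$se^2 + abp$cov[1, 1] + mu^2 * abp$cov[2, 2] +
                         2 * mu * abp$cov[1, 2], 1e-12)) / abs(abp$mean[["beta"]])
      c(mu, sdv)
    }, numeric(2))
    lo <- min(stats_t[1, ] - 10 * stats_t[2, ])
    hi <- max(stats_t[1, ] + 10 * stats_t[2, ])
    d_grid <- seq(lo, hi, length.out = 2001L)
  }
  if (any(diff(d_grid) <= 0)) stop("d_grid must be strictly increasing")
  dens <- numeric(length(d_grid))
  for (j in seq_along(nodes))
    dens <- dens + wts[j] * conditional_dose_density(d_grid, laplace, patient,
                                                     nodes[j])
  mass <- trapz_integral(d_grid, dens)
  if (abs(mass - 1) > 0.01)
    stop(sprintf("density mass on the grid is %.4f; widen d_grid", mass))
  dens <- dens / mass
  if (truncate) {
    keep <- d_grid >= 0
    d_grid <- d_grid[keep]; dens <- dens[keep]
    dens <- dens / trapz_integral(d_grid, dens)
  }
  out <- structure(list(method = "integrate", grid = d_grid, density = dens,
                        n_t_nodes = length(nodes), level = level,
                        truncate = truncate, time_prior = prior,
                        patient = patient),
                   class = "dose_posterior")
  out$summary <- summarize_posterior(out, level)
  out
}

trapz_integral <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# CDF inversion on a (grid, density) pair by linear interpolation
grid_quantile <- function(x, dens, probs) {
  cw <- c(0, cumsum(diff(x) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2))
  cw <- cw / cw[length(cw)]
  keep <- !duplicated(cw)
  stats::approx(cw[keep], x[keep], xout = probs, rule = 2)$y
}

#' Summaries of a dose posterior
#'
#' Mean, median and equal-tailed credible interval of the marginal dose
#' posterior, by empirical quantiles for a simulated posterior or CDF
#' inversion for an integrated density. When the posterior was built with
#' \code{truncate = TRUE}, draws below zero are discarded first.
#'
#' @param dose_post a \code{dose_posterior}.
#' @param level credibility level (default 0.95, equal-tailed).
#' @return a data frame row: method, mean, median, ci_lo, ci_hi, level.
#' @export
summarize_posterior <- function(dose_post, level = 0.95) {
  stopifnot(inherits(dose_post, "dose_posterior"), level > 0, level < 1)
  pr <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  if (dose_post$method == "simulate") {
    d <- dose_post$draws
    d <- d[is.finite(d)]
    if (isTRUE(dose_post$truncate)) d <- d[d >= 0]
    if (length(d) == 0L)
      stop("no valid dose draws left to summarize (all negative or invalid)")
    q <- stats::quantile(d, pr, names = FALSE)
    mean_d <- mean(d)
  } else {
    q <- grid_quantile(dose_post$grid, dose_post$density, pr)
    mean_d <- trapz_integral(dose_post$grid, dose_post$grid * dose_post$density)
  }
  data.frame(method = dose_post$method, mean = mean_d, median = q[2],
             ci_lo = q[1], ci_hi = q[3], level = level)
}

#' @export
print.dose_posterior <- function(x, digits = 3, ...) {
  s <- x$summary
  cat(sprintf("Dose posterior (%s%s):\n", x$method,
              if (x$method == "simulate") sprintf(", m = %d", x$m) else
                sprintf(", %d time nodes", x$n_t_nodes)))
  cat(sprintf("  mean %.*f Gy, median %.*f Gy, %g%% CI (%.*f, %.*f) Gy\n",
              digits, s$mean, digits, s$median, 100 * s$level,
              digits, s$ci_lo, digits, s$ci_hi))
  invisible(x)
}
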