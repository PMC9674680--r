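#' Calibration-line coefficients at a fixed time
#'
#' At fixed post-irradiation time t, the mean surface is affine in dose:
#' \eqn{\mu(d \mid t) = \alpha_t + \beta_t d} with
#' \eqn{\alpha_t = \sum_k \omega_k c_k t^{u_k}} and
#' \eqn{\beta_t = \sum_k \omega_k a_k t^{v_k}}.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param t time(s) in hours, > 0.
#' @return a matrix with one row per time and columns \code{alpha}, \code{beta}.
#' @export
alpha_beta_point <- function(params, t) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(t <= 0)) stop("time t must be strictly positive")
  u <- if (params$shared_u) rep(params$u, params$K) else params$u
  tu <- exp(outer(log(t), u))                       # n x K
  tv <- exp(outer(log(t), params$v))
  cbind(alpha = drop(tu %*% (params$weights * params$c)),
        beta = drop(tv %*% (params$weights * params$a)))
}

#' Jacobian of (alpha_t, beta_t) with respect to the free parametrization
#'
#' Analytic 2 x p gradient of the map g = (g1, g2) = (alpha_t, beta_t)
#' composed with the free-to-natural transform (additive log-ratio weights,
#' log a, log c). Used by the delta method.
#'
#' @param free free-parameter vector.
#' @param t time in hours (scalar), > 0.
#' @param spec a \code{\link{mixture_spec}}.
#' @return a 2 x p matrix with rows \code{alpha}, \code{beta}.
#' @export
alpha_beta_gradient <- function(free, t, spec) {
  stopifnot(length(t) == 1L, t > 0)
  params <- free_to_params(free, spec)
  K <- spec$K
  u <- if (spec$shared_u) rep(params$u, K) else params$u
  w <- params$weights
  ca <- params$a * t^(params$v)       # per-component beta terms / weight
  cc <- params$c * t^u                # per-component alpha terms / weight
  alpha <- sum(w * cc); beta <- sum(w * ca)
  p <- n_free_params(spec)
  G <- matrix(0, 2, p, dimnames = list(c("alpha", "beta"), free_names(spec)))
  i <- 0L
  if (K > 1L) {
    for (j in seq_len(K - 1L)) {      # d/dz_j: omega_k (delta_kj - omega_j)
      G[1, j] <- w[j] * (cc[j] - alpha)
      G[2, j] <- w[j] * (ca[j] - beta)
    }
    i <- K - 1L
  }
  G[2, i + seq_len(K)] <- w * ca                     # d/d log a_k
  i <- i + K
  G[1, i + seq_len(K)] <- w * cc                     # d/d log c_k
  i <- i + K
  if (spec$shared_u) {
    G[1, i + 1L] <- sum(w * cc) * log(t)             # d alpha / d u
    i <- i + 1L
  } else {
    G[1, i + seq_len(K)] <- w * cc * log(t)
    i <- i + K
  }
  G[2, i + seq_len(K)] <- w * ca * log(t)            # d beta / d v_k
  G
}

#' Delta-method posterior of the calibration line at a fixed time
#'
#' Pushes the Laplace posterior \eqn{N_p(\phi^*, \hat\Sigma)} through
#' g = (alpha_t, beta_t) to first order: mean \eqn{g(\phi^*)}, covariance
#' \eqn{\nabla g \, \hat\Sigma \, \nabla g^T} (symmetrized).
#'
#' @param laplace a \code{\link{laplace_approx}} result.
#' @param t time in hours (scalar), > 0.
#' @return an object of class \code{alpha_beta_posterior} with \code{t},
#'   \code{mean} (named alpha, beta) and 2 x 2 \code{cov}.
#' @export
alpha_beta_posterior <- function(laplace, t) {
  stopifnot(inherits(laplace, "laplace_posterior"), length(t) == 1L, t > 0)
  mu <- drop(alpha_beta_point(laplace$params, t))
  G <- alpha_beta_gradient(laplace$mode, t, laplace$spec)
  V <- G %*% laplace$cov %*% t(G)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("delta-method covariance is not positive semi-definite")
  dimnames(V) <- list(c("alpha", "beta"), c("alpha", "beta"))
  structure(list(t = t, mean = c(alpha = mu[[1]], beta = mu[[2]]), cov = V),
            class = "alpha_beta_posterior")
}

#' Draw free-parameter vectors from a Laplace posterior
#'
#' Samples \eqn{N_p(\phi^*, \hat\Sigma)}; mainly used to cross-check the
#' delta method against a Monte-Carlo pushforward through (alpha_t, beta_t).
#'
#' @param laplace a \code{laplace_posterior}.
#' @param m number of draws.
#' @param seed integer seed, or NULL.
#' @return an m x p matrix of free vectors.
#' @export
draw_free_posterior <- function(laplace, m, seed = NULL) {
  stopifnot(inherits(laplace, "laplace_posterior"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  MASS::mvrnorm(m, mu = laplace$mode, Sigma = laplace$cov)
}

#' @export
print.alpha_beta_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Calibration line at t = %g h:\n", x$t))
  cat(sprintf("  alpha = %.*f (sd %.*f), beta = %.*f (sd %.*f), corr %.3f\n",
              digits, x$mean[1], digits, sqrt(x$cov[1, 1]),
              digits, x$mean[2], digits, sqrt(x$cov[2, 2]),
              x$cov[1, 2] / sqrt(x$cov[1, 1] * x$cov[2, 2])))
  invisible(x)
}
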