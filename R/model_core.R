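#' Mixture model specification
#'
#' Describes the structure of a K-component Poisson mixture whose component
#' means are dose-time surfaces \eqn{\lambda_k(d,t) = c_k t^{u_k} + a_k t^{v_k} d}.
#' When \code{shared_u} is \code{TRUE} the spontaneous-foci time exponent
#' \eqn{u} is common to all components.
#'
#' @param K number of mixture components (>= 1).
#' @param shared_u logical; do all components share one exponent u?
#' @return an object of class \code{mixture_spec}.
#' @examples
#' n_free_params(mixture_spec(4, shared_u = TRUE))  # 16
#' @export
mixture_spec <- function(K, shared_u = TRUE) {
  K <- as.integer(K)
  stopifnot(length(K) == 1L, K >= 1L, is.logical(shared_u), length(shared_u) == 1L)
  structure(list(K = K, shared_u = shared_u), class = "mixture_spec")
}

#' Number of free parameters of a mixture specification
#'
#' Counts K-1 weights (simplex constraint), K dose slopes a, K intercept
#' coefficients c, K (or 1, if shared) exponents u and K exponents v.
#'
#' @param spec a \code{\link{mixture_spec}}.
#' @return integer parameter count; 16 for K = 4 with a shared u.
#' @export
n_free_params <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  (spec$K - 1L) + 3L * spec$K + if (spec$shared_u) 1L else spec$K
}

#' Mixture parameter set
#'
#' Weights and per-component surface coefficients of the Poisson mixture.
#' Components are kept in canonical order (ascending dose slope \code{a}) to
#' resolve label switching; use \code{canonical = FALSE} to keep the order
#' given.
#'
#' @param weights mixing proportions, positive, summing to 1.
#' @param a per-component dose slope coefficients (> 0), length K.
#' @param c_ per-component spontaneous-rate coefficients (> 0), length K.
#' @param u time exponent(s) of the spontaneous term: length 1 (shared) or K.
#' @param v per-component time exponents of the dose term, length K.
#' @param canonical sort components ascending by \code{a}?
#' @return an object of class \code{mixture_params}.
#' @export
mixture_params <- function(weights, a, c_, u, v, canonical = TRUE) {
  K <- length(weights)
  stopifnot(K >= 1L, length(a) == K, length(c_) == K, length(v) == K,
            length(u) %in% c(1L, K))
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights >= 1 + 1e-12))
    stop("weights must lie in (0, 1)")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(a <= 0) || any(c_ <= 0)) stop("a and c must be strictly positive")
  if (any(!is.finite(c(a, c_, u, v)))) stop("non-finite parameter value")
  p <- structure(list(weights = as.numeric(weights) / sum(weights),
                      a = as.numeric(a), c = as.numeric(c_),
                      u = as.numeric(u), v = as.numeric(v),
                      K = as.integer(K), shared_u = length(u) == 1L),
                 class = "mixture_params")
  if (canonical) canonical_order(p) else p
}

#' @export
print.mixture_params <- function(x, digits = 4, ...) {
  cat(sprintf("Poisson mixture surface parameters (K = %d%s)\n", x$K,
              if (x$shared_u) ", shared u" else ""))
  u <- if (x$shared_u) rep(x$u, x$K) else x$u
  tab <- data.frame(weight = x$weights, a = x$a, c = x$c, u = u, v = x$v)
  print(round(tab, digits), ...)
  invisible(x)
}

#' Put mixture components in canonical order
#'
#' Sorts components ascending by the dose slope \code{a} (the coefficient most
#' likely to separate radiosensitivity subsets), permuting weights and all
#' per-component coefficients accordingly. The likelihood is invariant.
#'
#' @param params a \code{\link{mixture_params}}.
#' @return the same parameter set with components reordered.
#' @export
canonical_order <- function(params) {
  ord <- order(params$a)
  params$weights <- params$weights[ord]
  params$a <- params$a[ord]
  params$c <- params$c[ord]
  params$v <- params$v[ord]
  if (!params$shared_u) params$u <- params$u[ord]
  params
}

#' Specification implied by a parameter set
#' @param params a \code{\link{mixture_params}}.
#' @return the matching \code{\link{mixture_spec}}.
#' @export
spec_of <- function(params) mixture_spec(params$K, params$shared_u)

#' Component mean surface
#'
#' Expected foci count of mixture component k at dose d (Gy) and
#' post-irradiation time t (h): \eqn{c_k t^{u_k} + a_k t^{v_k} d}.
#' Vectorized over \code{d} and \code{t}.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param k component index in 1..K.
#' @param d dose in Gy, >= 0.
#' @param t time in hours, > 0 (negative exponents make t = 0 singular).
#' @return positive expected count(s).
#' @export
lambda_surface <- function(params, k, d, t) {
  stopifnot(inherits(params, "mixture_params"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > params$K)
    stop("component index k out of range")
  if (any(t <= 0)) stop("time t must be strictly positive")
  if (any(d < 0)) stop("dose d must be non-negative")
  uk <- if (params$shared_u) params$u else params$u[k]
  params$c[k] * t^uk + params$a[k] * t^(params$v[k]) * d
}

# K x n matrix of component means at paired (d, t); no input checks (hot path)
lambda_matrix <- function(params, d, t) {
  u <- if (params$shared_u) rep(params$u, params$K) else params$u
  tu <- exp(outer(u, log(t)))            # K x n
  tv <- exp(outer(params$v, log(t)))     # K x n
  params$c * tu + (params$a * tv) * rep(d, each = params$K)
}

#' Mixture probability mass function
#'
#' Probability of observing \code{y} foci in a cell irradiated at dose d and
#' scored at time t: \eqn{\sum_k \omega_k e^{-\lambda_k}\lambda_k^y / y!}.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param y non-negative integer count (vectorized).
#' @param d dose in Gy.
#' @param t time in hours.
#' @return probabilities in (0, 1].
#' @export
mixture_pmf <- function(params, y, d, t) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(y < 0) || any(y != round(y))) stop("y must be a non-negative integer")
  if (length(d) != 1L || length(t) != 1L) stop("d and t must be scalars here")
  lam <- drop(lambda_matrix(params, d, t))         # length K
  as.numeric(vapply(y, function(yy) sum(params$weights * stats::dpois(yy, lam)),
                    numeric(1)))
}

#' Calibration dataset of per-cell foci counts
#'
#' Validates and wraps a data frame with columns \code{foci_count} (non-negative
#' integer), \code{dose_gy} (>= 0) and \code{time_h} (> 0), one row per scored
#' cell. Counts are pre-aggregated by (dose, time) condition for fast repeated
#' likelihood evaluation.
#'
#' @param df a data frame with the three columns above; no missing values.
#' @return an object of class \code{calib_data} (a data frame).
#' @export
as_calibration_data <- function(df) {
  req <- c("foci_count", "dose_gy", "time_h")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("calibration data needs columns foci_count, dose_gy, time_h")
  df <- as.data.frame(df)[req]
  if (nrow(df) == 0L) stop("calibration data is empty")
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) stop("missing values in calibration data at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  y <- df$foci_count
  if (any(y < 0) || any(y != round(y)))
    stop("foci_count must be non-negative integers (first bad row: ",
         which(y < 0 | y != round(y))[1], ")")
  if (any(df$dose_gy < 0)) stop("dose_gy must be non-negative")
  if (any(df$time_h <= 0)) stop("time_h must be strictly positive")
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(df))),
                          by = list(dose_gy = df$dose_gy, time_h = df$time_h,
                                    foci_count = df$foci_count), FUN = sum)
  key <- paste(agg$dose_gy, agg$time_h)
  conds <- !duplicated(key)
  tab <- lapply(split(agg[c("foci_count", "n_cells")], key), as.list)
  cond_df <- unique(data.frame(key = key, dose_gy = agg$dose_gy,
                               time_h = agg$time_h))[c("key", "dose_gy", "time_h")]
  structure(df, class = c("calib_data", "data.frame"),
            conditions = cond_df, ytab = tab, N = nrow(df))
}

#' @export
print.calib_data <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Calibration dataset: %d cells, %d (dose, time) conditions\n",
              attr(x, "N"), nrow(cond)))
  cat(sprintf("  doses (Gy): %s\n", paste(sort(unique(x$dose_gy)), collapse = ", ")))
  cat(sprintf("  times (h):  %s\n", paste(sort(unique(x$time_h)), collapse = ", ")))
  invisible(x)
}

#' Log-likelihood of the Poisson mixture surface model
#'
#' Sum over cells of the log mixture pmf at each cell's (dose, time),
#' computed per aggregated condition with log-sum-exp stabilization.
#' Returns \code{-Inf} (not an error) when any component mean is non-positive
#' or non-finite, so optimizers treat such points as invalid.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param data a \code{\link{as_calibration_data}} object.
#' @return a finite log-likelihood, or \code{-Inf} at invalid parameter points.
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "mixture_params"), inherits(data, "calib_data"))
  cond <- attr(data, "conditions")
  ytab <- attr(data, "ytab")
  lw <- log(params$weights)
  K <- params$K
  ll <- 0
  for (j in seq_len(nrow(cond))) {
    lam <- drop(lambda_matrix(params, cond$dose_gy[j], cond$time_h[j]))
    if (any(!is.finite(lam)) || any(lam <= 0)) return(-Inf)
    yt <- ytab[[cond$key[j]]]
    y <- yt$foci_count
    lp <- matrix(stats::dpois(rep(y, each = K), lam, log = TRUE),
                 nrow = K) + lw
    mx <- lp[1, ]
    if (K > 1L) for (k in 2:K) mx <- pmax(mx, lp[k, ])
    ls <- mx + log(colSums(exp(lp - rep(mx, each = K))))
    ll <- ll + sum(yt$n_cells * ls)
  }
  ll
}

#' Population mean surface
#'
#' Expected foci count at (d, t) under the whole mixture,
#' \eqn{\mu(d \mid t) = \sum_k \omega_k \lambda_k(d,t) = \alpha_t + \beta_t d}:
#' affine in dose at any fixed time.
#'
#' @inheritParams lambda_surface
#' @param d dose in Gy (vectorized with t).
#' @param t time in hours (vectorized with d).
#' @return positive expected count(s).
#' @export
mean_surface <- function(params, d, t) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(t <= 0)) stop("time t must be strictly positive")
  if (any(d < 0)) stop("dose d must be non-negative")
  ab <- alpha_beta_point(params, t)
  unname(ab[, 1L] + ab[, 2L] * d)
}

#' Akaike information criterion at a fitted optimum
#'
#' \eqn{AIC = 2p - 2\,\log L} with p the free-parameter count of the
#' specification (simplex-constrained weights contribute K - 1).
#'
#' @param params fitted \code{\link{mixture_params}} (the optimum).
#' @param spec the \code{\link{mixture_spec}} that was fitted.
#' @param data the \code{calib_data} the model was fitted to.
#' @return AIC value; lower is better.
#' @export
model_aic <- function(params, spec, data) {
  2 * n_free_params(spec) - 2 * log_likelihood(params, data)
}
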