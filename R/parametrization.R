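# Unconstrained ("free") parametrization used for optimization and for the
# Laplace covariance: additive log-ratio weights (reference = component K),
# log a_k, log c_k, then u (one value when shared), then v_k.

#' Names of the free-parameter coordinates
#' @param spec a \code{\link{mixture_spec}}.
#' @return character vector of length \code{n_free_params(spec)}.
#' @export
free_names <- function(spec) {
  K <- spec$K
  nm <- character(0)
  if (K > 1L) nm <- paste0("alr_w", seq_len(K - 1L))
  nm <- c(nm, paste0("log_a", seq_len(K)), paste0("log_c", seq_len(K)))
  nm <- c(nm, if (spec$shared_u) "u" else paste0("u", seq_len(K)))
  c(nm, paste0("v", seq_len(K)))
}

#' Map a natural parameter set to the free vector
#' @param params a \code{\link{mixture_params}}.
#' @param spec a matching \code{\link{mixture_spec}}.
#' @return named numeric vector of length p.
#' @export
params_to_free <- function(params, spec = spec_of(params)) {
  stopifnot(params$K == spec$K, params$shared_u == spec$shared_u)
  K <- spec$K
  z <- if (K > 1L) log(params$weights[-K] / params$weights[K]) else numeric(0)
  out <- c(z, log(params$a), log(params$c), params$u, params$v)
  stats::setNames(out, free_names(spec))
}

#' Map a free vector back to natural parameters
#' @param free numeric vector of length \code{n_free_params(spec)}.
#' @param spec a \code{\link{mixture_spec}}.
#' @param canonical sort components canonically? Defaults to FALSE so that the
#'   coordinate layout of \code{free} is preserved round-trip.
#' @return a \code{\link{mixture_params}}.
#' @export
free_to_params <- function(free, spec, canonical = FALSE) {
  p <- n_free_params(spec)
  if (length(free) != p)
    stop(sprintf("free vector has length %d, expected %d", length(free), p))
  K <- spec$K
  i <- 0L
  z <- if (K > 1L) free[seq_len(K - 1L)] else numeric(0)
  i <- K - 1L
  ez <- exp(c(z, 0))
  w <- ez / sum(ez)
  a <- exp(free[i + seq_len(K)]); i <- i + K
  cc <- exp(free[i + seq_len(K)]); i <- i + K
  nu <- if (spec$shared_u) 1L else K
  u <- free[i + seq_len(nu)]; i <- i + nu
  v <- free[i + seq_len(K)]
  mixture_params(w, a, cc, u, v, canonical = canonical)
}
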