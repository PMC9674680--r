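#' Read a calibration CSV
#'
#' Expects a UTF-8 CSV with header \code{foci_count,dose_gy,time_h}, one row
#' per scored cell, no missing values.
#'
#' @param path file path.
#' @return a \code{calib_data}.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop("calibration CSV not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  as_calibration_data(df)
}

#' Write a calibration CSV
#' @param data a \code{calib_data} (or compatible data frame).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calibration_csv <- function(data, path) {
  df <- as.data.frame(data)[c("foci_count", "dose_gy", "time_h")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the calibration output file
#'
#' The complete hand-off from the calibrating laboratory to the estimating
#' laboratory: model structure, free-parametrization descriptor, posterior
#' mode (the calibration coefficients) and full covariance matrix, the log
#' posterior and AIC. For the K = 4 shared-u model this is 16 mode values
#' plus 136 unique covariance entries — 152 numbers in total.
#'
#' @param laplace a \code{laplace_posterior}.
#' @param path output path (JSON).
#' @param selection optional \code{\link{select_model}} table to embed.
#' @return the path, invisibly.
#' @export
write_calibration_file <- function(laplace, path, selection = NULL) {
  stopifnot(inherits(laplace, "laplace_posterior"))
  obj <- list(
    format_version = 1L,
    model = list(K = laplace$spec$K, shared_u = laplace$spec$shared_u),
    parametrization = laplace$parametrization,
    mode = as.numeric(laplace$mode),
    covariance = unname(laplace$cov),
    log_posterior = laplace$log_posterior_at_mode,
    aic = laplace$aic)
  if (!is.null(selection))
    obj$selection <- as.data.frame(selection)[c("K", "shared_u", "p",
                                                "log_lik", "aic", "status")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration output file
#' @param path JSON path written by \code{\link{write_calibration_file}}.
#' @return a \code{laplace_posterior}.
#' @export
read_calibration_file <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported calibration file format")
  spec <- mixture_spec(obj$model$K, obj$model$shared_u)
  p <- n_free_params(spec)
  mode <- as.numeric(obj$mode)
  if (length(mode) != p)
    stop(sprintf("calibration file has %d mode values, expected %d",
                 length(mode), p))
  Sigma <- matrix(as.numeric(obj$covariance), p, p)
  Sigma <- (Sigma + t(Sigma)) / 2
  nm <- free_names(spec)
  dimnames(Sigma) <- list(nm, nm)
  structure(list(mode = stats::setNames(mode, nm),
                 params = free_to_params(mode, spec, canonical = FALSE),
                 cov = Sigma, spec = spec, parametrization = nm,
                 log_posterior_at_mode = obj$log_posterior, aic = obj$aic,
                 condition_number = NA_real_, jittered = FALSE),
            class = "laplace_posterior")
}

#' Count of numbers shipped in a calibration output
#'
#' p mode values plus the p(p+1)/2 unique entries of the symmetric covariance.
#'
#' @param laplace a \code{laplace_posterior} (or a \code{mixture_spec}).
#' @return integer count; 152 for K = 4 with shared u.
#' @export
n_calibration_numbers <- function(laplace) {
  spec <- if (inherits(laplace, "mixture_spec")) laplace else laplace$spec
  p <- n_free_params(spec)
  as.integer(p + p * (p + 1) / 2)
}
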