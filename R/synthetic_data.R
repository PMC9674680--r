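#' Calibration experiment design
#'
#' The default mirrors the in-vitro calibration layout behind the method:
#' doses spanning 0-3 Gy, post-irradiation times spanning 0.5-24 h, and 500
#' cells scored per (dose, time) condition.
#'
#' @param doses dose levels in Gy (>= 0).
#' @param times scoring times in hours (> 0).
#' @param cells_per_condition cells scored per condition (>= 1).
#' @return an object of class \code{design_grid}.
#' @export
design_grid <- function(doses = c(0, 0.5, 1, 2, 3),
                        times = c(0.5, 1, 2, 4, 24),
                        cells_per_condition = 500) {
  stopifnot(all(doses >= 0), all(times > 0), cells_per_condition >= 1)
  structure(list(doses = doses, times = times,
                 cells_per_condition = as.integer(cells_per_condition)),
            class = "design_grid")
}

#' Reference parameter set for simulations
#'
#' A two-component mixture with a shared spontaneous-decay exponent, tuned to
#' realistic gamma-H2AX magnitudes: roughly 0.5-1 background focus per cell
#' and about 25 foci at 3 Gy scored 0.5 h after exposure, with foci decaying
#' over 24 h. These are fixture values for the generator, not estimates from
#' any experiment.
#'
#' @return a \code{\link{mixture_params}} with K = 2, shared u.
#' @export
example_mixture_params <- function() {
  mixture_params(weights = c(0.6, 0.4), a = c(3.0, 6.0), c_ = c(0.4, 0.8),
                 u = -0.3, v = c(-0.5, -0.9))
}

#' Simulate a calibration dataset from the mixture model
#'
#' For every cell in every (dose, time) condition: draw a component from the
#' mixture weights, then a Poisson count at that component's surface mean.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param grid a \code{\link{design_grid}}.
#' @param seed integer seed, or NULL.
#' @return a \code{calib_data} with
#'   \code{length(doses) * length(times) * cells_per_condition} rows.
#' @export
generate_calibration_data <- function(params, grid = design_grid(),
                                      seed = NULL) {
  stopifnot(inherits(params, "mixture_params"), inherits(grid, "design_grid"))
  if (!is.null(seed)) set.seed(seed)
  n <- grid$cells_per_condition
  rows <- vector("list", length(grid$doses) * length(grid$times))
  i <- 0L
  for (d in grid$doses) for (t in grid$times) {
    i <- i + 1L
    lam <- drop(lambda_matrix(params, d, t))
    k <- sample.int(params$K, n, replace = TRUE, prob = params$weights)
    rows[[i]] <- data.frame(foci_count = stats::rpois(n, lam[k]),
                            dose_gy = d, time_h = t)
  }
  as_calibration_data(do.call(rbind, rows))
}

#' Simulate a patient sample at a true dose and time
#'
#' Draws per-cell counts from the mixture at the (unknown to the analyst)
#' true exposure, and returns the aggregate summary that the estimating
#' laboratory would receive, together with the raw counts.
#'
#' @param params a \code{\link{mixture_params}}.
#' @param true_dose true absorbed dose in Gy (>= 0).
#' @param true_time true time since exposure in hours (> 0).
#' @param n_cells cells scored.
#' @param seed integer seed, or NULL.
#' @return a list with \code{summary} (a \code{\link{patient_summary}}) and
#'   \code{counts} (the raw per-cell counts).
#' @export
generate_patient_sample <- function(params, true_dose, true_time,
                                    n_cells = 500, seed = NULL) {
  stopifnot(true_dose >= 0, true_time > 0, n_cells >= 2)
  if (!is.null(seed)) set.seed(seed)
  lam <- drop(lambda_matrix(params, true_dose, true_time))
  k <- sample.int(params$K, n_cells, replace = TRUE, prob = params$weights)
  y <- stats::rpois(n_cells, lam[k])
  list(summary = patient_summary(mean_foci = mean(y), sd_foci = stats::sd(y),
                                 n_cells = n_cells),
       counts = y)
}
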