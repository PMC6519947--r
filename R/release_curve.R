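#' Release curve container
#'
#' Time series of drug concentration in the bottom well and cumulative
#' fraction of the initial depot load released into the well. The central
#' exchange format between the solver, the diffusivity fitter and the safety
#' classifier.
#'
#' @param times Sampling times, hours.
#' @param well_concentration Bottom-well drug concentration, mM.
#' @param fraction_released Cumulative fraction of the initial insert load
#'   found in the well, dimensionless in `[0, 1]`.
#' @return An object of class `release_curve` (also a data.frame with columns
#'   `time_h`, `well_concentration_mM`, `fraction_released`).
#' @export
release_curve <- function(times, well_concentration, fraction_released) {
  if (length(times) != length(well_concentration) ||
      length(times) != length(fraction_released)) {
    stop("`times`, `well_concentration` and `fraction_released` must have ",
         "equal lengths", call. = FALSE)
  }
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(well_concentration < 0)) {
    stop("`well_concentration` must be non-negative", call. = FALSE)
  }
  if (any(fraction_released < -1e-12 | fraction_released > 1 + 1e-9)) {
    stop("`fraction_released` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(time_h = as.numeric(times),
               well_concentration_mM = as.numeric(well_concentration),
               fraction_released = pmin(pmax(fraction_released, 0), 1)),
    class = c("release_curve", "data.frame")
  )
}

#' @export
print.release_curve <- function(x, ...) {
  cat("release_curve:", nrow(x), "time points,",
      sprintf("final release %.3g%% at %g h\n",
              100 * x$fraction_released[nrow(x)], x$time_h[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Concentration field container
#'
#' Axial concentration profile at one simulation time.
#'
#' @param node_positions Cell-center positions, m, strictly increasing.
#' @param node_concentrations Concentrations at the cell centers, mM.
#' @param time Simulation time, seconds.
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(node_positions, node_concentrations, time) {
  if (length(node_positions) != length(node_concentrations)) {
    stop("positions and concentrations must have equal length", call. = FALSE)
  }
  if (is.unsorted(node_positions, strictly = TRUE)) {
    stop("`node_positions` must be strictly increasing", call. = FALSE)
  }
  if (any(node_concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(
    list(node_positions = node_positions,
         node_concentrations = node_concentrations,
         time = time),
    class = "concentration_field"
  )
}
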