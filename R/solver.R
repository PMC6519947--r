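# 1D finite-volume diffusion solver for the transwell system.
#
# The 3D well is reduced to an axial model with a cross-sectional-area jump
# at the insert-well interface; face conductances are built from series
# resistances (half-cell resistances, harmonic in D), which makes the scheme
# flux-continuous at the depot-media interface and exactly conservative.

# negative concentrations within this band (mM) are round-off and clipped;
# anything larger is a solver failure
NEG_TOL_MM <- 1e-12

face_conductances <- function(mesh, d_cell, membrane_permeability) {
  n <- mesh$n
  dxl <- mesh$width[-n]
  dxr <- mesh$width[-1]
  resist <- dxl / (2 * d_cell[-n]) + dxr / (2 * d_cell[-1])
  if (is.finite(membrane_permeability)) {
    resist[mesh$membrane_face] <- resist[mesh$membrane_face] +
      1 / membrane_permeability
  }
  mesh$face_area / resist # m^3/s
}

# generator matrix L with (dc/dt) = L c, built from face conductances
diffusion_generator <- function(mesh, g_face) {
  n <- mesh$n
  L <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    gi <- g_face[i]
    L[i, i] <- L[i, i] - gi / mesh$volume[i]
    L[i, i + 1L] <- L[i, i + 1L] + gi / mesh$volume[i]
    L[i + 1L, i + 1L] <- L[i + 1L, i + 1L] - gi / mesh$volume[i + 1L]
    L[i + 1L, i] <- L[i + 1L, i] + gi / mesh$volume[i + 1L]
  }
  L
}

#' Simulate drug release from the depot into the bottom well
#'
#' Solves the 1D diffusion equation over the transwell mesh with piecewise
#' diffusivity — the construct's effective diffusivity inside the depot, the
#' drug's media diffusivity everywhere else — no-flux boundaries at the top
#' and bottom, and flux continuity at internal interfaces. Drug starts
#' confined to the depot at the construct's initial concentration. Time
#' integration is implicit (backward Euler by default, Crank-Nicolson
#' optional) with a constant step, so the per-step propagator is factorized
#' once.
#'
#' @param geometry A [transwell_geometry()].
#' @param drug A [drug_properties()].
#' @param construct A [construct_spec()].
#' @param config A [simulation_config()].
#' @return An object of class `release_result`: list with `curve` (a
#'   [release_curve()] at the configured output times), `fields` (list of
#'   [concentration_field()]), `mesh`, and the input specs.
#' @export
simulate_release <- function(geometry, drug, construct,
                             config = simulation_config()) {
  stopifnot(inherits(geometry, "transwell_geometry"),
            inherits(drug, "drug_properties"),
            inherits(construct, "construct_spec"),
            inherits(config, "simulation_config"))
  mesh <- build_mesh(geometry, config)
  d_cell <- ifelse(mesh$domain == "depot",
                   construct$effective_diffusivity, drug$diffusivity_media)
  g_face <- face_conductances(mesh, d_cell, config$membrane_permeability)
  L <- diffusion_generator(mesh, g_face)
  n <- mesh$n
  dt <- config$dt

  propagator <- tryCatch(
    switch(config$scheme,
      backward_euler = solve(diag(n) - dt * L),
      crank_nicolson = solve(diag(n) - (dt / 2) * L) %*%
        (diag(n) + (dt / 2) * L)
    ),
    error = function(e) {
      stop("linear solve for the time-step propagator failed (", # nocov
           conditionMessage(e), "); check mesh and diffusivities",
           call. = FALSE)
    }
  )

  c0 <- ifelse(mesh$domain == "depot", construct$initial_concentration, 0)
  out_steps <- round(config$output_times * 3600 / dt)
  n_steps <- max(out_steps)

  fields <- vector("list", length(out_steps))
  conc <- c0
  take <- match(0, out_steps)
  if (!is.na(take)) fields[[take]] <- conc
  if (n_steps > 0) {
    want <- rep(NA_integer_, n_steps)
    want[out_steps[out_steps > 0]] <- which(out_steps > 0)
    for (k in seq_len(n_steps)) {
      conc <- propagator %*% conc
      if (!is.na(want[k])) fields[[want[k]]] <- as.numeric(conc)
    }
  }

  fields <- lapply(seq_along(out_steps), function(i) {
    ci <- as.numeric(fields[[i]])
    if (min(ci) < -NEG_TOL_MM) {
      stop(sprintf(
        "negative concentration %.3g mM at t = %g h exceeds the round-off floor; time integration is unstable for this configuration",
        min(ci), config$output_times[i]), call. = FALSE)
    }
    concentration_field(mesh$position, pmax(ci, 0), config$output_times[i] * 3600)
  })

  m0 <- construct$initial_concentration *
    sum(mesh$volume[mesh$domain == "depot"])
  well <- mesh$domain == "well_media"
  v_well <- sum(mesh$volume[well])
  well_mass <- vapply(fields, function(f) {
    sum(mesh$volume[well] * f$node_concentrations[well])
  }, numeric(1))

  curve <- release_curve(
    times = config$output_times,
    well_concentration = well_mass / v_well,
    fraction_released = if (m0 > 0) pmin(well_mass / m0, 1) else rep(0, length(well_mass))
  )

  structure(
    list(curve = curve, fields = fields, mesh = mesh,
         geometry = geometry, drug = drug, construct = construct,
         config = config),
    class = "release_result"
  )
}

#' @export
print.release_result <- function(x, ...) {
  cat("release_result:", x$construct$form, "construct, C0 =",
      x$construct$initial_concentration, "mM, D_eff =",
      format(x$construct$effective_diffusivity), "m^2/s\n")
  print(x$curve)
  invisible(x)
}

#' Total drug mass at each output time
#'
#' Integrates the concentration fields over the mesh; used to verify mass
#' conservation of the closed system.
#'
#' @param result A `release_result`.
#' @return Numeric vector of drug amounts (mol) at each output time.
#' @export
total_mass <- function(result) {
  stopifnot(inherits(result, "release_result"))
  vapply(result$fields, function(f) {
    sum(result$mesh$volume * f$node_concentrations)
  }, numeric(1))
}

#' Cumulative percent release into the bottom well
#'
#' Fraction of the initial insert drug load found in the bottom well at each
#' output time: `(amount in well at t) / (initial amount in insert)`.
#'
#' @param x A `release_result` (fractions recomputed by integrating the
#'   stored fields over the well cells) or a [release_curve()] (its
#'   `fraction_released` column is returned).
#' @param ... Unused.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
percent_release <- function(x, ...) UseMethod("percent_release")

#' @export
percent_release.release_curve <- function(x, ...) x$fraction_released

#' @export
percent_release.release_result <- function(x, ...) {
  m0 <- x$construct$initial_concentration *
    sum(x$mesh$volume[x$mesh$domain == "depot"])
  if (m0 <= 0) {
    stop("percent release is undefined for a zero initial drug amount",
         call. = FALSE)
  }
  well <- x$mesh$domain == "well_media"
  vapply(x$fields, function(f) {
    sum(x$mesh$volume[well] * f$node_concentrations[well]) / m0
  }, numeric(1))
}

#' Cell-apparent concentration time series
#'
#' Concentration at the bottom boundary of the well — the exposure the cells
#' seeded at the well bottom actually see — taken as the bottom-most cell's
#' concentration at each output time.
#'
#' @param x A `release_result` or a nonempty list of [concentration_field()].
#' @return `data.frame` with columns `time_h` and `concentration_mM`.
#' @export
cell_apparent_concentration <- function(x) {
  fields <- if (inherits(x, "release_result")) x$fields else x
  if (!is.list(fields) || length(fields) == 0) {
    stop("need a nonempty list of concentration fields", call. = FALSE)
  }
  data.frame(
    time_h = vapply(fields, function(f) f$time / 3600, numeric(1)),
    concentration_mM = vapply(fields, function(f) {
      f$node_concentrations[length(f$node_concentrations)]
    }, numeric(1))
  )
}
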