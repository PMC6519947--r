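#' Transwell insert/well geometry
#'
#' Physical description of a transwell culture system reduced to an axial
#' (1D) model: a permeable-membrane insert of cross-sectional area
#' `insert_membrane_area` holding a fluid column of depth `insert_fluid_depth`
#' (the top `depot_thickness` of which is occupied by the drug depot),
#' suspended over a well of cross-sectional area `well_cross_area` with fluid
#' depth `well_fluid_depth`. All quantities are SI (m, m^2).
#'
#' Defaults are catalog-typical dimensions for a 24-well transwell insert:
#' 0.33 cm^2 membrane, 1.9 cm^2 well, 100 uL insert fluid, 600 uL well fluid,
#' with the depot filling the whole insert column.
#'
#' @param insert_membrane_area Insert membrane (and insert fluid column)
#'   cross-sectional area in m^2.
#' @param insert_fluid_depth Depth of the fluid column inside the insert, m.
#' @param well_cross_area Well cross-sectional area, m^2.
#' @param well_fluid_depth Depth of the fluid in the bottom well, m.
#' @param depot_thickness Axial thickness of the drug depot at the top of the
#'   insert column, m. Must not exceed `insert_fluid_depth`.
#' @param plate_format `"well24"` or `"well96"` (metadata label).
#' @return An object of class `transwell_geometry`.
#' @export
transwell_geometry <- function(insert_membrane_area = 0.33e-4,
                               insert_fluid_depth = 100e-9 / 0.33e-4,
                               well_cross_area = 1.9e-4,
                               well_fluid_depth = 600e-9 / 1.9e-4,
                               depot_thickness = insert_fluid_depth,
                               plate_format = c("well24", "well96")) {
  plate_format <- match.arg(plate_format)
  for (nm in c("insert_membrane_area", "insert_fluid_depth",
               "well_cross_area", "well_fluid_depth", "depot_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (depot_thickness > insert_fluid_depth * (1 + 1e-12)) {
    stop("`depot_thickness` must not exceed `insert_fluid_depth`", call. = FALSE)
  }
  structure(
    list(
      insert_membrane_area = insert_membrane_area,
      insert_fluid_depth = insert_fluid_depth,
      well_cross_area = well_cross_area,
      well_fluid_depth = well_fluid_depth,
      depot_thickness = min(depot_thickness, insert_fluid_depth),
      plate_format = plate_format
    ),
    class = "transwell_geometry"
  )
}

#' Catalog-typical 96-well transwell geometry
#'
#' 0.143 cm^2 membrane, 0.32 cm^2 well, 75 uL insert fluid, 235 uL well fluid.
#'
#' @param depot_thickness Depot thickness, m; defaults to the full insert column.
#' @return A `transwell_geometry`.
#' @export
transwell_geometry_96 <- function(depot_thickness = NULL) {
  d_ins <- 75e-9 / 0.143e-4
  transwell_geometry(
    insert_membrane_area = 0.143e-4,
    insert_fluid_depth = d_ins,
    well_cross_area = 0.32e-4,
    well_fluid_depth = 235e-9 / 0.32e-4,
    depot_thickness = if (is.null(depot_thickness)) d_ins else depot_thickness,
    plate_format = "well96"
  )
}

#' Derived compartment volumes of a transwell geometry
#'
#' @param geometry A `transwell_geometry`.
#' @return Named list with `depot`, `insert` (full insert column, depot
#'   included), `well` and `total` volumes in m^3.
#' @export
geometry_volumes <- function(geometry) {
  stopifnot(inherits(geometry, "transwell_geometry"))
  v_insert <- geometry$insert_membrane_area * geometry$insert_fluid_depth
  v_well <- geometry$well_cross_area * geometry$well_fluid_depth
  list(
    depot = geometry$insert_membrane_area * geometry$depot_thickness,
    insert = v_insert,
    well = v_well,
    total = v_insert + v_well
  )
}

#' Drug transport properties
#'
#' @param name Drug label.
#' @param diffusivity_media Free diffusivity of the drug in culture media,
#'   m^2/s.
#' @param molar_mass Molar mass, g/mol (metadata only).
#' @return An object of class `drug_properties`.
#' @export
drug_properties <- function(name = "bupivacaine",
                            diffusivity_media = 1e-10,
                            molar_mass = 288.4) {
  if (!is.numeric(diffusivity_media) || length(diffusivity_media) != 1L ||
      !is.finite(diffusivity_media) || diffusivity_media <= 0) {
    stop("`diffusivity_media` must be a single positive finite number",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), diffusivity_media = diffusivity_media,
         molar_mass = molar_mass),
    class = "drug_properties"
  )
}

#' Drug depot (construct) specification
#'
#' Describes what sits in the transwell insert: a free-solution bolus, drug
#' loaded in liposomes, or liposomes embedded in an alginate hydrogel. The
#' depot is modelled as a single homogeneous layer with one effective
#' diffusivity; for a bolus the effective diffusivity must equal the drug's
#' media diffusivity.
#'
#' @param form `"bolus"`, `"liposome"` or `"liposome_alginate"`.
#' @param initial_concentration Initial drug concentration inside the depot,
#'   mM (numerically equal to mol/m^3).
#' @param effective_diffusivity Effective diffusivity of drug escape through
#'   the depot, m^2/s.
#' @param depot_volume Depot volume in m^3, or `NULL` to derive it from the
#'   geometry (`insert_membrane_area * depot_thickness`) at simulation time.
#' @param drug Optional `drug_properties`; when supplied and `form = "bolus"`,
#'   `effective_diffusivity` is checked against `diffusivity_media`.
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(form = c("liposome_alginate", "liposome", "bolus"),
                           initial_concentration = 1,
                           effective_diffusivity = 8.5e-15,
                           depot_volume = NULL,
                           drug = NULL) {
  form <- match.arg(form)
  if (!is.numeric(initial_concentration) || initial_concentration < 0) {
    stop("`initial_concentration` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(effective_diffusivity) || effective_diffusivity <= 0 ||
      !is.finite(effective_diffusivity)) {
    stop("`effective_diffusivity` must be a positive finite number",
         call. = FALSE)
  }
  if (!is.null(depot_volume) && (!is.numeric(depot_volume) || depot_volume <= 0)) {
    stop("`depot_volume` must be positive when given", call. = FALSE)
  }
  if (form == "bolus" && !is.null(drug) &&
      abs(effective_diffusivity - drug$diffusivity_media) >
        1e-9 * drug$diffusivity_media) {
    stop("for a bolus the effective diffusivity must equal the drug's ",
         "media diffusivity", call. = FALSE)
  }
  structure(
    list(form = form,
         initial_concentration = initial_concentration,
         effective_diffusivity = effective_diffusivity,
         depot_volume = depot_volume),
    class = "construct_spec"
  )
}

#' Simulation configuration
#'
#' @param dt Time step in seconds (default 10 s).
#' @param t_end End time in seconds; defaults to the last output time.
#' @param output_times Strictly increasing output times in hours.
#' @param nodes_depot Number of mesh cells in the depot (>= 3).
#' @param nodes_media Number of mesh cells in the media (insert media below
#'   the depot plus the well; >= 3).
#' @param scheme Time integration scheme: `"backward_euler"` (default,
#'   unconditionally stable at the 10 s step) or `"crank_nicolson"`.
#' @param membrane_permeability Optional membrane permeability coefficient in
#'   m/s applied at the insert-well interface; `Inf` (default) treats the
#'   membrane as freely permeable.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 10,
                              output_times = c(0, 1, 2, 4, 12, 24, 48, 96),
                              t_end = max(output_times) * 3600,
                              nodes_depot = 20,
                              nodes_media = 40,
                              scheme = c("backward_euler", "crank_nicolson"),
                              membrane_permeability = Inf) {
  scheme <- match.arg(scheme)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (length(output_times) < 1L || is.unsorted(output_times, strictly = TRUE)) {
    stop("`output_times` must be strictly increasing", call. = FALSE)
  }
  if (any(output_times * 3600 > t_end + 1e-9)) {
    stop("all `output_times` must be <= `t_end`", call. = FALSE)
  }
  if (nodes_depot < 3 || nodes_media < 3) {
    stop("node counts must be >= 3", call. = FALSE)
  }
  if (membrane_permeability <= 0) {
    stop("`membrane_permeability` must be positive (use Inf for a freely ",
         "permeable membrane)", call. = FALSE)
  }
  structure(
    list(dt = dt, t_end = t_end, output_times = as.numeric(output_times),
         nodes_depot = as.integer(nodes_depot),
         nodes_media = as.integer(nodes_media),
         scheme = scheme,
         membrane_permeability = membrane_permeability),
    class = "simulation_config"
  )
}

#' Closed-system equilibrium concentration
#'
#' For a closed transwell system with no uptake, all drug eventually
#' equilibrates to a uniform concentration `C0 * V_depot / (V_insert + V_well)`.
#' Used as the analytic long-time check for the solver.
#'
#' @param geometry A `transwell_geometry`.
#' @param construct A `construct_spec`.
#' @return Equilibrium concentration in mM.
#' @export
equilibrium_concentration <- function(geometry, construct) {
  vols <- geometry_volumes(geometry)
  v_depot <- if (is.null(construct$depot_volume)) vols$depot else construct$depot_volume
  construct$initial_concentration * v_depot / vols$total
}
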