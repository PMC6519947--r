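# Parameter-file loading with unit checking, and CSV/TIFF readers/writers.
# All internal computation is SI (m, s; concentrations in mM = mol/m^3);
# hours and mM appear only at the I/O boundary.

EXPECTED_UNITS <- list(
  geometry = c(insert_membrane_area = "m^2", insert_fluid_depth = "m",
               well_cross_area = "m^2", well_fluid_depth = "m",
               depot_thickness = "m"),
  drug = c(diffusivity_media = "m^2/s", molar_mass = "g/mol"),
  construct = c(initial_concentration = "mM", effective_diffusivity = "m^2/s",
                depot_volume = "m^3"),
  config = c(dt = "s", output_times = "h", t_end = "s",
             membrane_permeability = "m/s")
)

check_quantity <- function(x, section, field) {
  unit <- EXPECTED_UNITS[[section]][[field]]
  if (!is.list(x) || is.null(x$value) || is.null(x$unit)) {
    stop("field `", section, ".", field, "` must be written as ",
         "{value: ..., unit: \"", unit, "\"}", call. = FALSE)
  }
  if (!identical(as.character(x$unit), unit)) {
    stop("field `", section, ".", field, "` has unit '", x$unit,
         "' but must be '", unit, "'", call. = FALSE)
  }
  as.numeric(x$value)
}

take_fields <- function(section_data, section, plain = character(0)) {
  known <- c(names(EXPECTED_UNITS[[section]]), plain)
  unknown <- setdiff(names(section_data), known)
  if (length(unknown)) {
    stop("unknown key(s) in `", section, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (nm in names(section_data)) {
    out[[nm]] <- if (nm %in% plain) section_data[[nm]] else
      check_quantity(section_data[[nm]], section, nm)
  }
  out
}

#' Load a typed parameter bundle from YAML or JSON
#'
#' Parses a parameter file describing the transwell geometry, drug,
#' construct and simulation configuration. Every physical quantity must be
#' written as `{value, unit}` with the expected SI unit string; unknown keys
#' are rejected with an error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `parameter_bundle` with elements `geometry`
#'   ([transwell_geometry()]), `drug` ([drug_properties()]), `construct`
#'   ([construct_spec()]), `config` ([simulation_config()]) and `metadata`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw),
                     c("geometry", "drug", "construct", "config", "metadata"))
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  g <- take_fields(raw$geometry, "geometry", plain = "plate_format")
  geometry <- tryCatch(
    do.call(transwell_geometry, g),
    error = function(e) stop("invalid `geometry`: ", conditionMessage(e),
                             call. = FALSE)
  )

  d <- take_fields(raw$drug, "drug", plain = "name")
  drug <- do.call(drug_properties, d)

  cn <- take_fields(raw$construct, "construct", plain = "form")
  construct <- do.call(construct_spec, cn)

  cf <- take_fields(raw$config, "config",
                    plain = c("nodes_depot", "nodes_media", "scheme"))
  config <- do.call(simulation_config, cf)

  structure(
    list(geometry = geometry, drug = drug, construct = construct,
         config = config,
         metadata = if (is.null(raw$metadata)) list() else raw$metadata),
    class = "parameter_bundle"
  )
}

#' Write a parameter bundle back to YAML or JSON
#'
#' Inverse of [load_parameters()]; the write-then-read round trip
#' reproduces the bundle.
#'
#' @param bundle A `parameter_bundle`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(bundle, path) {
  stopifnot(inherits(bundle, "parameter_bundle"))
  q <- function(value, unit) list(value = value, unit = unit)
  g <- bundle$geometry; d <- bundle$drug; cn <- bundle$construct
  cf <- bundle$config
  out <- list(
    geometry = list(
      plate_format = g$plate_format,
      insert_membrane_area = q(g$insert_membrane_area, "m^2"),
      insert_fluid_depth = q(g$insert_fluid_depth, "m"),
      well_cross_area = q(g$well_cross_area, "m^2"),
      well_fluid_depth = q(g$well_fluid_depth, "m"),
      depot_thickness = q(g$depot_thickness, "m")
    ),
    drug = list(
      name = d$name,
      diffusivity_media = q(d$diffusivity_media, "m^2/s"),
      molar_mass = q(d$molar_mass, "g/mol")
    ),
    construct = c(
      list(form = cn$form,
           initial_concentration = q(cn$initial_concentration, "mM"),
           effective_diffusivity = q(cn$effective_diffusivity, "m^2/s")),
      if (!is.null(cn$depot_volume)) {
        list(depot_volume = q(cn$depot_volume, "m^3"))
      }
    ),
    config = list(
      dt = q(cf$dt, "s"),
      t_end = q(cf$t_end, "s"),
      output_times = q(cf$output_times, "h"),
      nodes_depot = cf$nodes_depot,
      nodes_media = cf$nodes_media,
      scheme = cf$scheme
    ),
    metadata = bundle$metadata
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 15)
  }
  invisible(path)
}

#' Packaged transwell study parameters
#'
#' Loads the bundled parameter file for the bupivacaine liposome-alginate
#' depot in a 24-well transwell system (media diffusivity 1e-10 m^2/s,
#' fitted construct effective diffusivity 8.5e-15 m^2/s, 1 mM initial load,
#' sampling at 0/1/2/4/12/24/48/96 h with a 10 s implicit time step).
#'
#' @return A `parameter_bundle`.
#' @export
study_parameters <- function() {
  load_parameters(
    system.file("extdata", "bupivacaine_transwell_params.yaml",
                package = "depotsim", mustWork = TRUE)
  )
}

RELEASE_HEADER <- c("time_h", "well_concentration_mM", "fraction_released")

#' Read / write a release curve CSV
#'
#' Header must be exactly `time_h,well_concentration_mM,fraction_released`;
#' non-numeric cells (including locale comma decimals) are a parse error
#' naming the offending line rather than a silent misparse. The round trip
#' is lossless to at least 12 significant digits.
#'
#' @param path CSV path.
#' @return [read_release_csv()] returns a [release_curve()].
#' @export
read_release_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("release CSV has no data rows", call. = FALSE)
  if (!identical(trimws(lines[1]), paste(RELEASE_HEADER, collapse = ","))) {
    stop("release CSV header must be exactly `",
         paste(RELEASE_HEADER, collapse = ","), "` (got `", lines[1], "`)",
         call. = FALSE)
  }
  num_re <- "^[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?$"
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    if (!nzchar(trimws(lines[i]))) return(NULL)
    cells <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(cells) != 3 || !all(grepl(num_re, cells))) {
      stop("release CSV parse error at line ", i, ": `", lines[i], "`",
           call. = FALSE)
    }
    as.numeric(cells)
  })
  m <- do.call(rbind, rows)
  release_curve(m[, 1], m[, 2], m[, 3])
}

#' @rdname read_release_csv
#' @param curve A [release_curve()].
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  lines <- c(paste(RELEASE_HEADER, collapse = ","),
             sprintf("%.15g,%.15g,%.15g", curve$time_h,
                     curve$well_concentration_mM, curve$fraction_released))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a z-stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice (32-bit float, intensities divided by the
#' sidecar's `intensity_scale`); the sidecar carries the physical metadata
#' the TIFF cannot.
#'
#' @param stack A [zstack()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar` is given.
#' @param sidecar Optional sidecar path.
#' @return [read_zstack_tiff()] returns a [zstack()].
#' @export
write_zstack_tiff <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "zstack"))
  scale <- max(abs(stack$voxels), 1e-12)
  pages <- lapply(seq_len(dim(stack$voxels)[3]), function(z) {
    pmax(stack$voxels[, , z] / scale, 0)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_xy_um = stack$pixel_size_xy,
         z_spacing_um = stack$z_spacing,
         bead_diameter_nominal_um = stack$bead_diameter_nominal,
         intensity_scale = scale),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zstack_tiff
#' @export
read_zstack_tiff <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar with pixel size and z-spacing: ", sidecar,
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- pages[[z]] * meta$intensity_scale
  zstack(vox, pixel_size_xy = meta$pixel_size_xy_um,
         z_spacing = meta$z_spacing_um,
         bead_diameter_nominal = meta$bead_diameter_nominal_um)
}

#' Write a centroid set to CSV
#'
#' Columns `x_um,y_um,z_um,region_size_px` (size `NA` when unknown).
#'
#' @param centroids A [centroid_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids_csv <- function(centroids, path) {
  stopifnot(inherits(centroids, "centroid_set"))
  df <- as.data.frame(centroids$points)
  df$region_size_px <- if (is.null(centroids$region_sizes)) NA_integer_ else
    as.integer(centroids$region_sizes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
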