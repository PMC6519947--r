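#' Build the axial finite-volume mesh for a transwell system
#'
#' Discretizes the axial coordinate from the top of the insert fluid column
#' (x = 0) down to the bottom of the well into contiguous cells. The depot
#' occupies the top `depot_thickness` of the insert and gets `nodes_depot`
#' cells; the remaining media (insert media below the depot, if any, plus the
#' well) shares `nodes_media` cells allocated proportionally to length. The
#' cell cross-sectional area steps from the insert membrane area to the well
#' cross-area at the insert-well (membrane) face.
#'
#' Depot cells are geometrically graded (ratio `grading`) so the finest cell
#' sits at the depot's release face: for slow depots the early-time release
#' is controlled by a thin boundary layer of thickness `sqrt(D_eff * t)`
#' (micrometres for hydrogel-scale diffusivities), which a uniform mesh at
#' practical cell counts cannot resolve. Media cells are uniform.
#'
#' @param geometry A [transwell_geometry()].
#' @param config A [simulation_config()].
#' @param grading Geometric width ratio between successive depot cells
#'   (coarsest at the no-flux top, finest at the release face); 1 gives a
#'   uniform depot mesh.
#' @return An object of class `transwell_mesh`: list with `position` (cell
#'   centers, m), `width`, `area`, `volume`, `domain` (one of `"depot"`,
#'   `"insert_media"`, `"well_media"` per cell), `face_area` (area assigned to
#'   each interior face), and `membrane_face` (index of the insert-well face,
#'   faces numbered between cells i and i+1).
#' @export
build_mesh <- function(geometry, config, grading = 1.35) {
  stopifnot(inherits(geometry, "transwell_geometry"),
            inherits(config, "simulation_config"))
  l_depot <- geometry$depot_thickness
  l_insmed <- geometry$insert_fluid_depth - l_depot
  l_well <- geometry$well_fluid_depth

  # allocate media cells between insert media and well by length
  n_media <- config$nodes_media
  if (l_insmed > 1e-15) {
    n_insmed <- max(1L, min(n_media - 1L,
                            round(n_media * l_insmed / (l_insmed + l_well))))
  } else {
    n_insmed <- 0L
  }
  n_well <- n_media - n_insmed

  # depot: geometric grading, widest cell at the top (no-flux) boundary,
  # finest at the release face
  nd <- config$nodes_depot
  if (grading > 1) {
    w_depot <- grading^((nd - 1):0)
    w_depot <- w_depot * (l_depot / sum(w_depot))
  } else {
    w_depot <- rep(l_depot / nd, nd)
  }
  w_insmed <- rep(if (n_insmed > 0) l_insmed / n_insmed else numeric(0),
                  n_insmed)
  w_well <- rep(l_well / n_well, n_well)
  width <- c(w_depot, w_insmed, w_well)
  edges <- c(0, cumsum(width))
  pos <- (edges[-1] + edges[-length(edges)]) / 2
  domain <- c(
    rep("depot", config$nodes_depot),
    rep("insert_media", n_insmed),
    rep("well_media", n_well)
  )
  area <- ifelse(domain == "well_media",
                 geometry$well_cross_area, geometry$insert_membrane_area)
  n <- length(pos)
  membrane_face <- config$nodes_depot + n_insmed # face between insert & well
  # drug crosses the membrane through the insert membrane area
  face_area <- pmin(area[-n], area[-1])

  structure(
    list(position = pos, width = width, area = area, volume = area * width,
         domain = domain, face_area = face_area,
         membrane_face = membrane_face, n = n,
         geometry = geometry),
    class = "transwell_mesh"
  )
}

#' @export
print.transwell_mesh <- function(x, ...) {
  cat("transwell_mesh:", x$n, "cells (",
      sum(x$domain == "depot"), "depot /",
      sum(x$domain == "insert_media"), "insert media /",
      sum(x$domain == "well_media"), "well )\n")
  cat(sprintf("  span %.3g m, membrane face at index %d\n",
              sum(x$width), x$membrane_face))
  invisible(x)
}
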