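# Shared fixtures: fast solver configurations and the closed-form
# two-compartment membrane-exchange oracle.

# coarse-but-sufficient configuration for property tests: same physics,
# smaller problem
coarse_config <- function(output_times = c(0, 1, 2, 4, 12, 24, 48, 96),
                          dt = 120, nodes_depot = 6, nodes_media = 8, ...) {
  simulation_config(dt = dt, output_times = output_times,
                    nodes_depot = nodes_depot, nodes_media = nodes_media, ...)
}

# simple two-compartment geometry: equal areas, depot = whole insert
two_comp_geometry <- function() {
  transwell_geometry(
    insert_membrane_area = 1e-4, insert_fluid_depth = 1e-3,
    well_cross_area = 1e-4, well_fluid_depth = 2e-3,
    depot_thickness = 1e-3
  )
}

# closed-form solution of the two-compartment membrane-exchange ODE:
# V1 c1' = -g (c1 - c2), V2 c2' = g (c1 - c2), g = A_membrane * permeability
two_comp_solution <- function(t_s, c0, v1, v2, g) {
  c_eq <- c0 * v1 / (v1 + v2)
  tau <- 1 / (g * (1 / v1 + 1 / v2))
  list(
    insert = c_eq + (c0 - c_eq) * exp(-t_s / tau),
    well = c_eq * (1 - exp(-t_s / tau)),
    tau = tau, c_eq = c_eq
  )
}

# deterministic hand-built z-stack: blobs pasted on a black background
blob_stack <- function(blobs, img_px = 32, n_slices = 1, pixel_size_xy = 2,
                       level = 100) {
  vox <- array(0, c(img_px, img_px, n_slices))
  for (b in blobs) {
    vox[b$rows, b$cols, b$slice] <- level
  }
  zstack(vox, pixel_size_xy = pixel_size_xy, z_spacing = 50)
}
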