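test_that("vanishing depot diffusivity keeps drug in the depot", {
  res <- simulate_release(
    transwell_geometry(), drug_properties(),
    construct_spec("liposome_alginate", 1, effective_diffusivity = 1e-22),
    coarse_config()
  )
  expect_true(all(res$curve$fraction_released < 1e-4))
  expect_true(all(cell_apparent_concentration(res)$concentration_mM < 1e-4))
})

test_that("mass is conserved to 0.1% at every output time", {
  for (d_eff in c(8.5e-15, 1e-12, 1e-10)) {
    res <- simulate_release(
      transwell_geometry(), drug_properties(),
      construct_spec("liposome_alginate", 1, effective_diffusivity = d_eff),
      coarse_config()
    )
    m <- total_mass(res)
    expect_lt(max(abs(m / m[1] - 1)), 1e-3)
  }
})

test_that("cumulative release is monotone non-decreasing in time", {
  res <- simulate_release(
    transwell_geometry(), drug_properties(),
    construct_spec("liposome_alginate", 1, 8.5e-15), coarse_config()
  )
  expect_true(all(diff(res$curve$fraction_released) >= -1e-12))
})

test_that("long-time solution converges to the equilibrium concentration", {
  geo <- transwell_geometry()
  cons <- construct_spec("bolus", 1, 1e-10)
  res <- simulate_release(
    geo, drug_properties(), cons,
    coarse_config(output_times = c(0, 48, 300), dt = 300)
  )
  c_eq <- equilibrium_concentration(geo, cons)
  final <- res$fields[[3]]$node_concentrations
  expect_true(all(abs(final - c_eq) / c_eq < 0.01))
})

test_that("release is ordered in the effective diffusivity", {
  geo <- transwell_geometry()
  drug <- drug_properties()
  curves <- lapply(c(1e-15, 1e-14, 1e-13, 1e-12), function(d) {
    simulate_release(geo, drug, construct_spec("liposome_alginate", 1, d),
                     coarse_config())$curve$fraction_released
  })
  for (i in seq_len(length(curves) - 1)) {
    expect_true(all(curves[[i]] <= curves[[i + 1]] + 1e-12))
  }
})

test_that("doubling the mesh changes 96 h release by under 1%", {
  geo <- transwell_geometry()
  drug <- drug_properties()
  cons <- construct_spec("liposome_alginate", 1, 8.5e-15)
  f1 <- simulate_release(geo, drug, cons,
                         simulation_config(dt = 60))$curve$fraction_released
  f2 <- simulate_release(
    geo, drug, cons,
    simulation_config(dt = 60, nodes_depot = 40, nodes_media = 80)
  )$curve$fraction_released
  expect_lt(abs(f2[8] - f1[8]) / f1[8], 0.01)
})

test_that("solver matches the closed-form two-compartment exchange ODE", {
  # well-mixed compartments (large diffusivities) exchanging through a
  # finite-permeability membrane reduce to the two-compartment ODE
  geo <- two_comp_geometry()
  perm <- 1e-6
  d_big <- 1e-7
  out_h <- c(0, 0.05, 0.1, 0.25, 0.5, 1)
  res <- simulate_release(
    geo, drug_properties(diffusivity_media = d_big),
    construct_spec("liposome_alginate", 1, effective_diffusivity = d_big),
    simulation_config(dt = 5, output_times = out_h, nodes_depot = 3,
                      nodes_media = 3, membrane_permeability = perm)
  )
  oracle <- two_comp_solution(out_h * 3600, c0 = 1, v1 = 1e-7, v2 = 2e-7,
                              g = 1e-4 * perm)
  sim_well <- res$curve$well_concentration_mM
  # also exercised at the coarsest mesh: two cells per compartment
  expect_lt(max(abs(sim_well[-1] - oracle$well[-1]) / oracle$well[-1]), 0.05)
  cell <- cell_apparent_concentration(res)$concentration_mM
  expect_lt(max(abs(cell[-1] - oracle$well[-1]) / oracle$well[-1]), 0.05)
  insert_conc <- vapply(res$fields, function(f) {
    mean(f$node_concentrations[res$mesh$domain == "depot"])
  }, numeric(1))
  expect_lt(max(abs(insert_conc - oracle$insert) / oracle$insert), 0.05)
})

test_that("percent release matches an independent trapezoidal mass oracle", {
  res <- simulate_release(
    transwell_geometry(), drug_properties(),
    construct_spec("liposome_alginate", 1, 1e-13),
    simulation_config(dt = 60, output_times = c(0, 24, 96))
  )
  frac <- percent_release(res)
  # trapezoidal integration of c(x) * A over the well cells, vs the cell-sum
  mesh <- res$mesh
  well <- which(mesh$domain == "well_media")
  m0 <- 1 * sum(mesh$volume[mesh$domain == "depot"])
  x <- mesh$position[well]
  a_well <- mesh$area[well][1]
  for (i in 2:3) {
    cw <- res$fields[[i]]$node_concentrations[well]
    trapz <- sum(diff(x) * (head(cw, -1) + tail(cw, -1)) / 2) * a_well
    # add the half-cell stubs at the well ends (midpoint rule)
    stubs <- a_well * (cw[1] + cw[length(cw)]) * mesh$width[well][1] / 2
    expect_equal(frac[i], (trapz + stubs) / m0, tolerance = 0.03)
  }
  expect_true(all(frac >= 0 & frac <= 1))
})

test_that("percent release limits: no transport and full equilibration", {
  geo <- two_comp_geometry()
  # all drug still in depot
  res0 <- simulate_release(
    geo, drug_properties(), construct_spec("liposome_alginate", 1, 1e-22),
    coarse_config(output_times = c(0, 1))
  )
  expect_equal(percent_release(res0)[2], 0, tolerance = 1e-6)
  # fully equilibrated closed system releases V_well / V_total
  res1 <- simulate_release(
    geo, drug_properties(), construct_spec("bolus", 1, 1e-10),
    coarse_config(output_times = c(0, 400), dt = 600)
  )
  expect_equal(percent_release(res1)[2], 2e-7 / 3e-7, tolerance = 0.01)
})

test_that("percent release is undefined for an empty depot", {
  res <- simulate_release(
    transwell_geometry(), drug_properties(),
    construct_spec("liposome_alginate", 0, 8.5e-15),
    coarse_config(output_times = c(0, 1))
  )
  expect_error(percent_release(res), "zero initial")
})

test_that("cell-apparent concentration reads the bottom boundary", {
  mesh_pos <- c(0.5, 1.5, 2.5) * 1e-3
  f_uniform <- concentration_field(mesh_pos, rep(0.05, 3), 0)
  expect_equal(cell_apparent_concentration(list(f_uniform))$concentration_mM,
               0.05)
  expect_error(cell_apparent_concentration(list()), "nonempty")
})

test_that("crank-nicolson agrees with backward euler at the study step", {
  geo <- transwell_geometry()
  drug <- drug_properties()
  cons <- construct_spec("liposome_alginate", 1, 1e-13)
  be <- simulate_release(geo, drug, cons, coarse_config())
  cn <- simulate_release(geo, drug, cons, coarse_config(scheme = "crank_nicolson"))
  expect_equal(cn$curve$fraction_released, be$curve$fraction_released,
               tolerance = 0.02)
})
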