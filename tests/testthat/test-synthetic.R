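test_that("generators are pure functions of their specs", {
  cfg <- coarse_config()
  s <- release_gen_spec(config = cfg, seed = 7)
  expect_identical(generate_release_data(s), generate_release_data(s))

  bs <- bead_gen_spec(n_spots = 10, seed = 7)
  b1 <- generate_bead_stack(bs)
  b2 <- generate_bead_stack(bs)
  expect_identical(b1$stack$voxels, b2$stack$voxels)
  expect_identical(b1$truth$points, b2$truth$points)

  vs <- viability_gen_spec(n_replicates = 4, seed = 7)
  expect_identical(generate_viability_data(vs), generate_viability_data(vs))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_bead_stack(bead_gen_spec(n_spots = 5, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free release generation is exactly the forward model", {
  cfg <- coarse_config()
  spec <- release_gen_spec(true_diffusivity = 3e-14, config = cfg,
                           noise_model = "none")
  curve <- generate_release_data(spec)
  cons <- construct_spec("liposome_alginate", 1, 3e-14)
  ref <- simulate_release(spec$geometry, spec$drug, cons,
                          coarse_config())$curve
  expect_identical(curve$well_concentration_mM, ref$well_concentration_mM)
  expect_identical(curve$fraction_released, ref$fraction_released)
})

test_that("multiplicative noise has the declared per-point CV", {
  cfg <- coarse_config(output_times = c(0, 12, 24, 48, 96))
  specs <- lapply(1:100, function(s) {
    release_gen_spec(config = cfg, sample_times = c(0, 12, 24, 48, 96),
                     noise_model = "multiplicative_gaussian",
                     noise_scale = 0.02, seed = s)
  })
  curves <- lapply(specs, generate_release_data)
  conc <- do.call(rbind, lapply(curves, function(x) x$well_concentration_mM))
  cv <- apply(conc[, -1], 2, function(x) sd(x) / mean(x))
  expect_true(all(cv > 0.015 & cv < 0.025))
})

test_that("noiseless round trip recovers the diffusivity within 1%", {
  cfg <- coarse_config()
  spec <- release_gen_spec(true_diffusivity = 8.5e-15, config = cfg,
                           noise_model = "none")
  obs <- generate_release_data(spec)
  fit <- fit_diffusivity(obs, spec$geometry, spec$drug, spec$construct,
                         config = cfg)
  expect_lt(abs(fit$d_hat - 8.5e-15) / 8.5e-15, 0.01)
})

test_that("bead diameters follow the 200 um +/- 5% size model", {
  d <- sample_bead_diameters(500, bead_gen_spec(seed = 1))
  expect_lt(abs(mean(d) - 200), 1)
  expect_gt(sd(d), 8)   # nominal sd is 10 um (5% CV)
  expect_lt(sd(d), 12)
  # the full generator draws from the same model
  b <- generate_bead_stack(bead_gen_spec(n_spots = 0, seed = 1))
  expect_equal(b$bead_diameter, sample_bead_diameters(1, bead_gen_spec(seed = 1)))
})

test_that("a spotless bead is background plus noise with empty truth", {
  b <- generate_bead_stack(bead_gen_spec(n_spots = 0, noise_sd = 0, seed = 2))
  expect_equal(nrow(b$truth$points), 0L)
  expect_true(all(b$stack$voxels == 20))
  expect_equal(binarize_and_segment(b$stack)$n_regions, 0L)
})

test_that("an isolated spot survives the full pipeline within one voxel", {
  b <- generate_bead_stack(bead_gen_spec(n_spots = 1, noise_sd = 0, seed = 3))
  seg <- binarize_and_segment(b$stack)
  expect_equal(seg$n_regions, 1L)
  cs <- extract_centroids(seg, bead_center = b$bead_center,
                          bead_radius = b$bead_diameter / 2)
  err <- sqrt(sum((cs$points[1, ] - b$truth$points[1, ])^2))
  expect_lt(err, b$stack$pixel_size_xy) # sub-voxel in xy, exact in z
})

test_that("segmentation round trip recovers at least 95% of spots", {
  stats <- lapply(1:6, function(s) {
    b <- generate_bead_stack(bead_gen_spec(n_spots = 30, seed = s))
    seg <- binarize_and_segment(b$stack)
    cs <- extract_centroids(seg, bead_center = b$bead_center,
                            bead_radius = b$bead_diameter / 2)
    match_centroids(b$truth, cs, max_dist = 2 * b$stack$pixel_size_xy)
  })
  recall <- vapply(stats, function(x) x$recall, numeric(1))
  err <- vapply(stats, function(x) x$mean_error, numeric(1))
  expect_gte(mean(recall), 0.95)
  expect_lt(mean(err), 2) # mean centroid error below one 2-um pixel
})

test_that("homogeneously seeded beads pass the uniformity test", {
  # mirrors the even-distribution finding on real beads: uniform placement
  # should rarely reject CSR
  p_vals <- vapply(1:10, function(s) {
    b <- generate_bead_stack(bead_gen_spec(n_spots = 30, seed = 100 + s))
    seg <- binarize_and_segment(b$stack)
    cs <- extract_centroids(seg, bead_center = b$bead_center,
                            bead_radius = b$bead_diameter / 2)
    csr_uniformity_test(cs, n_monte_carlo = 199, seed = s)$csr_p_value
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("viability replicates converge to the tabulated means", {
  spec <- viability_gen_spec(n_replicates = 10000, seed = 4)
  dat <- generate_viability_data(spec)
  cell <- dat[dat$concentration_mM == 0.1 & dat$exposure_h == 48, ]
  expect_equal(nrow(cell), 10000L)
  expect_lt(abs(mean(cell$viability_pct) - 90) / 90, 0.01)
  ctrl <- dat[dat$concentration_mM == 0 & dat$exposure_h == 24, ]
  expect_lt(abs(mean(ctrl$viability_pct) - 100), 1)
  # SEM-implied spread: sd = sem * sqrt(n_experiments) = 2 * sqrt(3) at this cell
  expect_equal(sd(cell$viability_pct), 2 * sqrt(3), tolerance = 0.05)
})

test_that("generated replicates feed the group comparison end to end", {
  dat <- generate_viability_data(viability_gen_spec(n_replicates = 6, seed = 12))
  sub <- dat[dat$exposure_h == 48 & dat$concentration_mM %in% c(0, 1), ]
  cg <- compare_groups(data.frame(group = paste0(sub$concentration_mM, "mM"),
                                  value = sub$viability_pct))
  expect_lte(cg$lsd$p_value[1], 0.05) # 100% vs 38% viability at n = 6
})

test_that("generator specs validate their inputs", {
  expect_error(release_gen_spec(noise_scale = -1), "noise_scale")
  expect_error(release_gen_spec(true_diffusivity = 0), "positive")
  expect_error(bead_gen_spec(n_spots = -2), "n_spots")
  expect_error(viability_gen_spec(n_replicates = 1), "n_replicates")
})
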