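# Seeded synthetic-data generators: noisy release curves from a known
# diffusivity, bead z-stacks with ground-truth liposome centroids, and
# replicate viability datasets. Every generator is a pure function of its
# spec (seed included).

#' Release-curve generator specification
#'
#' @param true_diffusivity Generating effective diffusivity, m^2/s.
#' @param geometry,drug,construct,config Forward-model inputs; the
#'   construct's `effective_diffusivity` is replaced by `true_diffusivity`
#'   and `config$output_times` by `sample_times`.
#' @param noise_model `"none"`, `"additive_gaussian"` (sd =
#'   `noise_scale * max(concentration)`) or `"multiplicative_gaussian"`
#'   (per-point CV = `noise_scale`).
#' @param noise_scale Noise scale as a fraction; default 0.02 (2%
#'   multiplicative), a typical HPLC quantification error.
#' @param seed RNG seed.
#' @param sample_times Sampling times, hours; default the study grid
#'   `{0, 1, 2, 4, 12, 24, 48, 96}`.
#' @return An object of class `release_gen_spec`.
#' @export
release_gen_spec <- function(true_diffusivity = 8.5e-15,
                             geometry = transwell_geometry(),
                             drug = drug_properties(),
                             construct = construct_spec(),
                             config = simulation_config(),
                             noise_model = c("multiplicative_gaussian",
                                             "additive_gaussian", "none"),
                             noise_scale = 0.02,
                             seed = 1,
                             sample_times = c(0, 1, 2, 4, 12, 24, 48, 96)) {
  noise_model <- match.arg(noise_model)
  if (noise_scale < 0) stop("`noise_scale` must be >= 0", call. = FALSE)
  if (true_diffusivity <= 0) {
    stop("`true_diffusivity` must be positive", call. = FALSE)
  }
  structure(
    list(true_diffusivity = true_diffusivity, geometry = geometry,
         drug = drug, construct = construct, config = config,
         noise_model = noise_model, noise_scale = noise_scale,
         seed = as.integer(seed), sample_times = sample_times),
    class = "release_gen_spec"
  )
}

#' Generate a (noisy) synthetic release curve
#'
#' Runs the forward transwell simulation at the spec's true diffusivity and
#' applies the seeded noise model to the well concentration; the fraction
#' released is rescaled consistently. With `noise_model = "none"` the output
#' is exactly the forward-model curve.
#'
#' @param spec A [release_gen_spec()].
#' @return A [release_curve()].
#' @export
generate_release_data <- function(spec) {
  stopifnot(inherits(spec, "release_gen_spec"))
  cons <- spec$construct
  cons$effective_diffusivity <- spec$true_diffusivity
  cfg <- spec$config
  cfg$output_times <- spec$sample_times
  cfg$t_end <- max(spec$sample_times) * 3600
  res <- simulate_release(spec$geometry, spec$drug, cons, cfg)
  curve <- res$curve
  if (spec$noise_model == "none" || spec$noise_scale == 0) return(curve)
  conc <- withr_seed(spec$seed, {
    n <- nrow(curve)
    switch(spec$noise_model,
      additive_gaussian = curve$well_concentration_mM +
        stats::rnorm(n, 0, spec$noise_scale * max(curve$well_concentration_mM)),
      multiplicative_gaussian = curve$well_concentration_mM *
        (1 + stats::rnorm(n, 0, spec$noise_scale))
    )
  })
  conc <- pmax(conc, 0)
  scale <- ifelse(curve$well_concentration_mM > 0,
                  conc / curve$well_concentration_mM, 1)
  release_curve(curve$time_h, conc,
                pmin(curve$fraction_released * scale, 1))
}

#' Bead z-stack generator specification
#'
#' Emulates confocal imaging of a single alginate microbead: a bead diameter
#' drawn from Normal(mean, cv * mean), liposome spots placed uniformly at
#' random in the bead sphere, rendered as 2D Gaussians on the nearest of the
#' 50-um-spaced slices, over a uniform background with Gaussian noise.
#'
#' @param n_spots Number of liposome spots (default 30).
#' @param bead_diameter_mean Mean bead diameter, um (default 200).
#' @param bead_diameter_cv Coefficient of variation of the diameter
#'   (default 0.05, i.e. "+/- 5%").
#' @param pixel_size_xy Lateral pixel size, um (default 2).
#' @param img_px Image side length, pixels (default 128).
#' @param z_spacing Slice spacing, um (default 50).
#' @param spot_sigma_px Gaussian spot sigma, pixels (default 1; sub-resolution
#'   liposomes render at the scale of the microscope point-spread function).
#' @param spot_amplitude Peak spot intensity above background (default 200).
#' @param background_level Background intensity (default 20).
#' @param noise_sd Gaussian noise sd (default 5).
#' @param full_scale Detector full-scale value at which intensities clip
#'   (default 255, 8-bit acquisition); overlapping spots saturate rather
#'   than summing without bound.
#' @param seed RNG seed.
#' @return An object of class `bead_gen_spec`.
#' @export
bead_gen_spec <- function(n_spots = 30, bead_diameter_mean = 200,
                          bead_diameter_cv = 0.05, pixel_size_xy = 2,
                          img_px = 128, z_spacing = 50, spot_sigma_px = 1,
                          spot_amplitude = 200, background_level = 20,
                          noise_sd = 5, full_scale = 255, seed = 1) {
  if (n_spots < 0) stop("`n_spots` must be >= 0", call. = FALSE)
  if (bead_diameter_cv < 0) stop("`bead_diameter_cv` must be >= 0", call. = FALSE)
  structure(
    list(n_spots = as.integer(n_spots),
         bead_diameter_mean = bead_diameter_mean,
         bead_diameter_cv = bead_diameter_cv,
         pixel_size_xy = pixel_size_xy, img_px = as.integer(img_px),
         z_spacing = z_spacing, spot_sigma_px = spot_sigma_px,
         spot_amplitude = spot_amplitude,
         background_level = background_level, noise_sd = noise_sd,
         full_scale = full_scale, seed = as.integer(seed)),
    class = "bead_gen_spec"
  )
}

#' Generate a synthetic bead z-stack with ground truth
#'
#' @param spec A [bead_gen_spec()].
#' @return List of class `synthetic_bead`: `stack` (a [zstack()]), `truth`
#'   (a [centroid_set()] of bead-centered ground-truth centroids, with z
#'   snapped to the rendered slice), `bead_diameter` (um), `bead_center`
#'   (image um coordinates), and `spec`.
#' @export
generate_bead_stack <- function(spec) {
  stopifnot(inherits(spec, "bead_gen_spec"))
  withr_seed(spec$seed, {
    diam <- stats::rnorm(1, spec$bead_diameter_mean,
                         spec$bead_diameter_cv * spec$bead_diameter_mean)
    diam <- max(diam, 4 * spec$pixel_size_xy)
    radius <- diam / 2

    n_slices <- max(1L, floor(diam / spec$z_spacing) + 1L)
    # slices symmetric about the bead equator
    slice_z <- (seq_len(n_slices) - (n_slices + 1) / 2) * spec$z_spacing
    side_um <- spec$img_px * spec$pixel_size_xy
    if (side_um < diam) {
      stop("image field smaller than the bead; increase `img_px`",
           call. = FALSE)
    }
    center_xy <- side_um / 2

    # uniform placement in the bead sphere; retry draws that land outside
    # the rendered slice span or image margin (bounded retries)
    pts <- matrix(numeric(0), 0, 3)
    margin <- 4 * spec$spot_sigma_px * spec$pixel_size_xy
    tries <- 0L
    while (nrow(pts) < spec$n_spots) {
      tries <- tries + 1L
      if (tries > 100L * max(spec$n_spots, 1L)) {
        stop("could not place spots inside the image after bounded retries",
             call. = FALSE)
      }
      p <- runif_sphere(1, radius)
      if (abs(p[1]) > center_xy - margin || abs(p[2]) > center_xy - margin) next
      pts <- rbind(pts, p)
    }

    img <- array(spec$background_level, c(spec$img_px, spec$img_px, n_slices))
    truth <- matrix(numeric(0), 0, 3)
    if (spec$n_spots > 0) {
      slice_of <- vapply(pts[, 3], function(z) which.min(abs(slice_z - z)),
                         integer(1))
      half <- ceiling(4 * spec$spot_sigma_px)
      for (i in seq_len(nrow(pts))) {
        px <- (pts[i, 1] + center_xy) / spec$pixel_size_xy
        py <- (pts[i, 2] + center_xy) / spec$pixel_size_xy
        ix <- max(1, floor(px - half)):min(spec$img_px, ceiling(px + half))
        iy <- max(1, floor(py - half)):min(spec$img_px, ceiling(py + half))
        gx <- exp(-(ix - px)^2 / (2 * spec$spot_sigma_px^2))
        gy <- exp(-(iy - py)^2 / (2 * spec$spot_sigma_px^2))
        img[ix, iy, slice_of[i]] <- img[ix, iy, slice_of[i]] +
          spec$spot_amplitude * outer(gx, gy)
        truth <- rbind(truth, c(pts[i, 1], pts[i, 2], slice_z[slice_of[i]]))
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    img <- pmin(pmax(img, 0), spec$full_scale) # detector clipping

    stack <- zstack(img, pixel_size_xy = spec$pixel_size_xy,
                    z_spacing = spec$z_spacing,
                    bead_diameter_nominal = spec$bead_diameter_mean)
    structure(
      list(stack = stack,
           truth = centroid_set(truth, bead_radius = radius,
                                tol_um = spec$z_spacing),
           bead_diameter = diam,
           bead_center = c(center_xy, center_xy,
                           (n_slices + 1) / 2 * spec$z_spacing),
           spec = spec),
      class = "synthetic_bead"
    )
  })
}

#' Sample bead diameters from the generator's size model
#'
#' Convenience wrapper drawing `n` bead diameters exactly as
#' [generate_bead_stack()] does, without rendering images.
#'
#' @param n Number of beads.
#' @param spec A [bead_gen_spec()]; its seed seeds the draw.
#' @return Numeric vector of diameters, um.
#' @export
sample_bead_diameters <- function(n, spec = bead_gen_spec()) {
  withr_seed(spec$seed, {
    stats::rnorm(n, spec$bead_diameter_mean,
                 spec$bead_diameter_cv * spec$bead_diameter_mean)
  })
}

#' Viability replicate generator specification
#'
#' @param table A [viability_table()] supplying means and SEMs; default the
#'   packaged MSC bupivacaine table.
#' @param n_replicates Replicates to draw per (concentration, exposure)
#'   cell; >= 2.
#' @param n_experiments Replicate count the tabulated SEMs derive from
#'   (sd = sem * sqrt(n_experiments)); defaults to the table's value.
#' @param seed RNG seed.
#' @return An object of class `viability_gen_spec`.
#' @export
viability_gen_spec <- function(table = msc_viability_table(),
                               n_replicates = 4,
                               n_experiments = table$n_experiments,
                               seed = 1) {
  stopifnot(inherits(table, "viability_table"))
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  structure(
    list(table = table, n_replicates = as.integer(n_replicates),
         n_experiments = n_experiments, seed = as.integer(seed)),
    class = "viability_gen_spec"
  )
}

#' Generate replicate viability measurements
#'
#' Draws `n_replicates` values per table cell from
#' `Normal(mean, sem * sqrt(n_experiments))` — the per-experiment standard
#' deviation implied by the tabulated SEM. Cells with missing SEM use the
#' table-wide median SEM.
#'
#' @param spec A [viability_gen_spec()].
#' @return `data.frame` with columns `concentration_mM`, `exposure_h`,
#'   `replicate`, `viability_pct`.
#' @export
generate_viability_data <- function(spec) {
  stopifnot(inherits(spec, "viability_gen_spec"))
  tab <- spec$table
  sem <- tab$sem
  if (is.null(sem)) sem <- array(2, dim(tab$mean_viability))
  sem[!is.finite(sem)] <- stats::median(sem[is.finite(sem)])
  grid <- expand.grid(exposure_h = tab$exposure_times,
                      concentration_mM = tab$concentrations)
  withr_seed(spec$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      ti <- match(grid$exposure_h[i], tab$exposure_times)
      ci <- match(grid$concentration_mM[i], tab$concentrations)
      sd_i <- sem[ti, ci] * sqrt(spec$n_experiments)
      data.frame(
        concentration_mM = grid$concentration_mM[i],
        exposure_h = grid$exposure_h[i],
        replicate = seq_len(spec$n_replicates),
        viability_pct = stats::rnorm(spec$n_replicates,
                                     tab$mean_viability[ti, ci], sd_i)
      )
    }))
    rownames(out) <- NULL
    out
  })
}
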