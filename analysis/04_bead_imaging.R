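#!/usr/bin/env Rscript
# Bead imaging pipeline on synthetic microbeads: segment liposome spots in
# 50-um-spaced z-stacks, extract 3D centroids, and test spatial uniformity
# (complete spatial randomness) per bead.

suppressPackageStartupMessages(library(depotsim))
dir.create("results", showWarnings = FALSE)

n_beads <- 8
per_bead <- list()
for (s in seq_len(n_beads)) {
  b <- generate_bead_stack(bead_gen_spec(n_spots = 30, seed = 200 + s))
  seg <- binarize_and_segment(b$stack)
  cs <- extract_centroids(seg, bead_center = b$bead_center,
                          bead_radius = b$bead_diameter / 2)
  m <- match_centroids(b$truth, cs, max_dist = 2 * b$stack$pixel_size_xy)
  st <- csr_uniformity_test(cs, n_monte_carlo = 999, seed = s)
  if (s == 1) {
    write_zstack_tiff(b$stack, "results/example_bead.tif")
    write_centroids_csv(cs, "results/example_bead_centroids.csv")
  }
  per_bead[[s]] <- data.frame(
    bead = s, diameter_um = b$bead_diameter, n_truth = nrow(b$truth$points),
    n_segmented = seg$n_regions, recall = m$recall,
    centroid_error_um = m$mean_error,
    mean_nn_um = st$mean_nn_distance, csr_null_nn_um = st$null_mean_nn,
    csr_p = st$csr_p_value
  )
}
tab <- do.call(rbind, per_bead)
write.csv(tab, "results/bead_imaging_summary.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)

message(sprintf(
  "Across %d beads: %.0f%% of seeded spots recovered (mean centroid error %.2f um); %d/%d beads consistent with a uniform liposome distribution (CSR p > 0.05).",
  n_beads, 100 * mean(tab$recall), mean(tab$centroid_error_um),
  sum(tab$csr_p > 0.05), n_beads))
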