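#!/usr/bin/env Rscript
# Forward release simulations: how much bupivacaine reaches the bottom well
# from a free bolus vs the liposome-alginate construct, across the tested
# initial concentrations (0.01, 0.1, 1 mM), over 96 h in the 24-well
# transwell geometry.

suppressPackageStartupMessages(library(depotsim))
dir.create("results", showWarnings = FALSE)

params <- study_parameters()
doses <- c(0.01, 0.1, 1)

rows <- list()
for (dose in doses) {
  for (form in c("bolus", "liposome_alginate")) {
    cons <- construct_spec(
      form = form, initial_concentration = dose,
      effective_diffusivity = if (form == "bolus") {
        params$drug$diffusivity_media
      } else {
        params$construct$effective_diffusivity
      }
    )
    res <- simulate_release(params$geometry, params$drug, cons, params$config)
    out <- sprintf("results/release_%s_%gmM.csv", form, dose)
    write_release_csv(res$curve, out)
    rows[[length(rows) + 1]] <- data.frame(
      form = form, dose_mM = dose,
      release_96h_pct = 100 * res$curve$fraction_released[8],
      max_well_mM = max(res$curve$well_concentration_mM),
      max_cell_apparent_mM =
        max(cell_apparent_concentration(res)$concentration_mM)
    )
  }
}
summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, "results/release_summary.csv", row.names = FALSE)

message("Release by 96 h and peak exposures:")
print(summary_tab, digits = 3, row.names = FALSE)
message(
  "A free bolus equilibrates toward V_well/V_total (~86% of the load in the ",
  "well) within hours, while the liposome-alginate construct releases only ",
  "a few percent of its load over 4 days: the depot, not the transwell ",
  "geometry, limits transport.")
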