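#!/usr/bin/env Rscript
# Group-comparison statistics on replicate viability data: one-way ANOVA
# with Fisher LSD post hoc contrasts (alpha = 0.05) across delivery forms,
# using synthetic replicates at effect sizes taken from the dose-response
# table (bolus exposure near 1 mM vs construct exposure near 0 mM).

suppressPackageStartupMessages(library(depotsim))
dir.create("results", showWarnings = FALSE)

tab <- msc_viability_table()
spec <- viability_gen_spec(table = tab, n_replicates = 6, seed = 15)
dat <- generate_viability_data(spec)

# delivery forms mapped to the 48 h exposures their simulated cell-apparent
# concentrations imply: bolus ~ 1 mM, liposome ~ 0.5 mM, construct ~ control
sub48 <- dat[dat$exposure_h == 48, ]
groups <- list(
  bolus = sub48$viability_pct[sub48$concentration_mM == 1],
  liposome = sub48$viability_pct[sub48$concentration_mM == 0.5],
  construct = sub48$viability_pct[sub48$concentration_mM == 0]
)
cg <- compare_groups(groups, alpha = 0.05)
print(cg)

jsonlite::write_json(
  list(group_means = as.list(cg$group_means),
       f_statistic = cg$f_statistic, p_value = cg$p_value,
       df_between = cg$df[1], df_within = cg$df[2], lsd = cg$lsd),
  "results/viability_anova.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

lsd_bc <- cg$lsd[cg$lsd$group1 == "bolus" & cg$lsd$group2 == "construct", ]
message(sprintf(
  "At n = 6 replicates, viability differs across delivery forms (F(%d,%d) = %.1f, p = %.2g); bolus vs construct LSD p = %.2g.",
  cg$df[1], cg$df[2], cg$f_statistic, cg$p_value, lsd_bc$p_value))
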