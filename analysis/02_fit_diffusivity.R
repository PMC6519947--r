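#!/usr/bin/env Rscript
# Effective-diffusivity estimation: emulate an in vitro release experiment
# (2% multiplicative measurement noise at the 8 sampling times), then
# recover the construct's effective diffusivity by SSE minimization and
# check the noiseless round trip.

suppressPackageStartupMessages(library(depotsim))
dir.create("results", showWarnings = FALSE)

params <- study_parameters()
d_true <- params$construct$effective_diffusivity

noiseless <- generate_release_data(release_gen_spec(
  true_diffusivity = d_true, geometry = params$geometry, drug = params$drug,
  construct = params$construct, config = params$config,
  noise_model = "none", sample_times = params$config$output_times
))
fit0 <- fit_diffusivity(noiseless, params$geometry, params$drug,
                        params$construct, config = params$config)

noisy <- generate_release_data(release_gen_spec(
  true_diffusivity = d_true, geometry = params$geometry, drug = params$drug,
  construct = params$construct, config = params$config,
  noise_model = "multiplicative_gaussian", noise_scale = 0.02, seed = 7,
  sample_times = params$config$output_times
))
write_release_csv(noisy, "results/synthetic_release_observed.csv")
fit1 <- fit_diffusivity(noisy, params$geometry, params$drug,
                        params$construct, config = params$config)

report <- list(
  d_true = d_true,
  noiseless = list(d_hat = fit0$d_hat, sse = fit0$sse,
                   log10_error = log10(fit0$d_hat) - log10(d_true),
                   n_evaluations = fit0$n_evaluations),
  noisy_2pct = list(d_hat = fit1$d_hat, sse = fit1$sse,
                    log10_se = fit1$log10_se,
                    n_evaluations = fit1$n_evaluations)
)
jsonlite::write_json(report, "results/diffusivity_fit.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

print(fit0); print(fit1)
message(sprintf(
  "Noiseless data return the generating diffusivity to %.2g in log10; with 2%% measurement noise the estimate moves to %.3g m^2/s.",
  abs(report$noiseless$log10_error), fit1$d_hat))
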