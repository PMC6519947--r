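# depotsim

Transwell release simulation and analysis for liposome-alginate anesthetic
depots.

Local anesthetics such as bupivacaine are toxic to co-administered
mesenchymal stromal cells (MSCs) at bolus concentrations. Embedding
bupivacaine-loaded liposomes in an alginate hydrogel produces a depot that
releases the drug over days instead of hours. `depotsim` is for researchers
evaluating such depots in transwell culture: it simulates drug transport
from the depot to the cells, estimates the depot's effective diffusivity
from release measurements, classifies exposure profiles against an MSC
viability dose-response table, and quantifies liposome distribution inside
alginate microbeads from confocal z-stacks.

## The model

Transport in the static, closed transwell system is Fickian diffusion on a
1D axial column with a cross-sectional area step at the insert-well
interface:

    A(x) dc/dt = d/dx ( A(x) D(x) dc/dx ),   no-flux ends,

with piecewise diffusivity: the depot's effective diffusivity `D_eff`
(default 8.5e-15 m^2/s, the value estimated from release data) inside the
alginate-liposome layer and the free media diffusivity `D_media = 1e-10
m^2/s` elsewhere. The solver is a conservative finite-volume scheme
(geometrically graded depot cells to resolve the `sqrt(D t)` release
boundary layer), stepped implicitly at 10 s. `D_eff` is estimated by
minimizing `SSE(D) = sum_i (c_obs_i - c_sim_i(D))^2` over `log10 D` with
Brent's method at the study's sampling times {0, 1, 2, 4, 12, 24, 48, 96} h.
Safety logic: the largest tabulated dose keeping >= 90% MSC viability after
48 h exposure is 0.1 mM, and a release profile is safe when the
cell-apparent (well-bottom) concentration never crosses that ceiling. The
imaging module segments liposome spots per 50-um z-slice, extracts 3D
centroids, and tests spatial uniformity against a Monte-Carlo complete
spatial randomness (CSR) null.

## Worked example

```r
library(depotsim)

params <- study_parameters()            # packaged 24-well study parameters
res <- simulate_release(params$geometry, params$drug, params$construct,
                        params$config)  # 1 mM liposome-alginate construct
res$curve
#> release_curve: 8 time points, final release 2% at 96 h
#>   time_h well_concentration_mM fraction_released
#> 1      0          0.0000000000       0.000000000
#> 2      1          0.0003324196       0.001994518
#> ...
#> 8     96          0.0033301637       0.019980984

cell <- cell_apparent_concentration(res)
classify_release_safety(cell, threshold = 0.1)
#> safety_report: max 0.003249 mM vs ceiling 0.1 mM -> SAFE

max_safe_concentration(msc_viability_table(), viability_floor = 90,
                       exposure = 48)
#> [1] 0.1

obs <- generate_release_data(release_gen_spec(
  true_diffusivity = 8.5e-15, config = params$config, noise_model = "none"))
fit_diffusivity(obs, params$geometry, params$drug, params$construct,
                config = params$config)
#> fit_result: D_hat = 8.511e-15 m^2/s (SSE = 9.497e-12 over 8 points)
#>   bounds [1e-18, 1e-10], 17 objective evaluations, converged: TRUE
```

Read: the 1 mM construct releases ~2% of its load in 4 days, its peak
cell-apparent concentration (0.0032 mM) sits far below the 0.1 mM
viability ceiling — the same 1 mM load as a free bolus peaks at 0.14 mM
and is classified unsafe — and the diffusivity fitter recovers a known
generating diffusivity to 0.1% from noiseless 8-point data.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin script
over the package writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_release.R` | bolus vs construct release at 0.01/0.1/1 mM |
| `02_fit_diffusivity.R` | diffusivity recovery from synthetic release data |
| `03_safety_classification.R` | safe-ceiling derivation + profile classification |
| `04_bead_imaging.R` | segmentation, centroids and CSR test on synthetic beads |
| `05_viability_statistics.R` | ANOVA + Fisher LSD across delivery forms |

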