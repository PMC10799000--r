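# dryq10

Partitioning and temperature sensitivity of soil organic and inorganic
carbon CO2 emissions in drylands.

Dryland soils hold large stocks of both organic carbon (SOC) and inorganic
carbonate carbon (SIC), and both emit CO2 as soils warm. Because the two
sources carry distinct carbon-isotope signatures (δ13C of organic matter is
strongly depleted relative to carbonate), closed-jar incubations that
measure CO2 accumulation together with its δ13C can be split into
SOC-derived and SIC-derived fluxes, and each source given its own
temperature sensitivity (Q10). `dryq10` is for biogeochemists and
ecosystem modellers who want that analysis chain as tested, reusable code:

* **gas flux** — closed-chamber emission rates from headspace CO2
  accumulation (ideal-gas arithmetic at jar temperature);
* **isotope partitioning** — the two-end-member mixing model
  δ13C_total = (1 − f_SIC)·δ13C_SOC + f_SIC·δ13C_SIC, with the 4.4 ‰
  diffusion correction and an optional temperature-fractionation hook;
* **Q10 fitting** — R = B·e^(kT), Q10 = e^(10k), log-linear OLS (NLS
  optional), with source-specific QC (R² > 0.95 SOC, > 0.85 SIC) and the
  substrate indices CAI and D_SOC;
* **gradient statistics** — Q10-vs-aridity regressions, paired
  moisture-treatment t tests, Holm-corrected factor correlations;
* **path analysis** — PCA composites of climate / physical / chemical /
  substrate variables, recursive path model with standardized
  direct / indirect / total effect decomposition and ML fit indices
  (χ², RMSEA, GFI);
* **upscaling** — the dryland carbon bookkeeping: heterotrophic
  respiration, warming-induced SIC emissions under alternative Q10s, and
  the aridity-offset arithmetic;
* **synthetic cohort** — a seeded generator of a full study (sites,
  soils, incubation gas series) with known ground truth, so the whole
  pipeline is verifiable end to end.

## Worked example

```r
library(dryq10)

cfg <- cohort_config(seed = 1L)      # 30 sites, 2 depths, 4 moistures
res <- run_all(cfg)

res$gradient[, c("depth", "source", "slope_per_0p1_ai", "r", "p_value")]
#>   depth   source slope_per_0p1_ai      r  p_value
#> 1 subsoil SOC               0.518  0.879 1.68e-10
#> 2 subsoil SIC              -0.439 -0.844 4.46e- 9
#> 3 topsoil SOC               0.540  0.884 9.67e-11
#> 4 topsoil SIC              -0.362 -0.742 2.70e- 6
```

Per 0.1 increase in aridity index (wetter sites), the fitted Q10 of
SOC-derived CO2 rises by ~0.5 while the Q10 of SIC-derived CO2 falls by
~0.4 — opposite moisture responses for the two carbon sources, in both
soil layers. The mean partitioned SIC contribution at 20 °C is recovered at
7.2 % (topsoil) and 11.1 % (subsoil), matching the generator's calibration.

The closing bookkeeping:

```r
up <- run_upscaling()
round(unlist(up[c("dryland_het_resp", "warming_flux_soc_q10",
                  "warming_flux_sic_q10", "underestimate_pct",
                  "soc_reduction", "sic_gain", "offset_pct")]), 2)
#>     dryland_het_resp warming_flux_soc_q10 warming_flux_sic_q10
#>                20.38                 3.19                 4.29
#>    underestimate_pct        soc_reduction             sic_gain
#>                25.63                 1.48                 0.35
#>           offset_pct
#>                26.67
```

Read: dryland heterotrophic respiration ≈ 20.4 Pg C yr⁻¹; under 4 °C of
warming, the SIC-derived increment is 3.2 Pg C yr⁻¹ if the SOC-mean Q10 is
(wrongly) used for SIC versus 4.3 Pg C yr⁻¹ with the SIC-mean Q10 — a
25.6 % underestimate; and per 0.1 decrease in aridity index the SOC-flux
reduction (1.5 Pg C yr⁻¹) is offset by ~26.7 % by the SIC-flux gain
(0.4 Pg C yr⁻¹, printed-rounding mode).

## The analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study pipeline on a synthetic cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort CSVs + config
Rscript analysis/02_flux_partition.R  # emission rates + isotope split
Rscript analysis/03_q10_fit.R         # per-sample-and-source Q10 fits
Rscript analysis/04_gradient_stats.R  # regressions, t tests, correlations
Rscript analysis/05_path_model.R      # composites, path models, effects
Rscript analysis/06_upscaling.R       # carbon bookkeeping
```

Every step is a thin wrapper over exported package functions; the methods
vignette (`vignettes/dryq10-methods.Rmd`) documents the models, the
generator's assumptions, and the numerical conventions.

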