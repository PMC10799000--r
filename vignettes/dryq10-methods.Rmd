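---
title: "Methods: partitioning and temperature sensitivity of dryland soil CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning and temperature sensitivity of dryland soil CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryq10)
```

## The problem

Dryland soils store carbon in two coupled pools: soil organic carbon (SOC)
and soil inorganic carbon (SIC, mostly calcium carbonate). Both release CO2
when soils warm — SOC through microbial decomposition, SIC through carbonate
dissolution — and the two responses need not have the same temperature
sensitivity (Q10) nor respond the same way to moisture. Because the two CO2
sources carry distinct carbon stable-isotope signatures (organic matter is
strongly depleted in 13C, carbonates are near 0 permil VPDB), a closed-jar
incubation that measures both the CO2 accumulation and its delta13C can be
split into SOC- and SIC-derived fluxes, and each source can be given its own
Q10.

`dryq10` implements that entire analysis chain — flux computation, isotope
partitioning, exponential temperature-response fitting, aridity-gradient
statistics, PCA-composite path analysis, and the closing global bookkeeping —
together with a synthetic-cohort generator with known ground truth, so every
stage can be verified end to end without access to any particular field
campaign's raw data.

## Models and procedures

### Closed-jar emission rates

Jars (250 mL, 50 g dry-weight soil) are flushed with CO2-free air, sealed,
and the headspace CO2 concentration difference over the step duration gives
the emission rate through the ideal-gas molar volume at the incubation
temperature:

$$ R \;=\; \Delta C \cdot 10^{-6} \cdot \frac{V_{head}}{V_m(T)} \cdot
   \frac{12.011 \cdot 10^{6}}{m \cdot \Delta t}
   \quad [\mu g\,C\,g^{-1}\,h^{-1}], $$

with $V_m(T) = 22.414 (T + 273.15)/273.15$ L mol$^{-1}$ at 1 atm. The
headspace volume is the jar volume minus soil mass over an assumed bulk
density (1.3 g cm$^{-3}$ by default) — the density is configuration, not a
measurement, and is kept auditable in `incubation_protocol()`. The 15 mL
headspace sample removed at the start is replaced by CO2-free air; with an
ideally flushed jar (initial concentration 0 ppm) this replacement has no
effect on the two-point difference, so the inversion ignores it. Negative
concentration differences are retained and flagged rather than clipped;
the fitting stage excludes them through its minimum-point rule.

### Two-end-member isotope partitioning

The delta13C of the total emitted CO2 is modelled as a linear mixture of the
two sources,

$$ \delta^{13}C_{total} = (1 - f_{SIC})\,\delta^{13}C_{SOC} +
   f_{SIC}\,\delta^{13}C_{SIC}, $$

inverted as $f_{SIC} = (\delta_{total} - \delta_{SOC}) /
(\delta_{SIC} - \delta_{SOC})$. Before inversion the emitted delta13C is
raised by a constant 4.4 permil diffusion fractionation (CO2 leaving the
soil is depleted relative to soil CO2), and the end members pass through a
linear temperature-fractionation hook $\delta + a + bT$ whose default
coefficients $(0, 0)$ make it a no-op — i.e. by default the delta13C of a
source and of its CO2 are taken as equal. Mixing is linear in delta units
rather than in isotope-ratio space; at the 20-permil separations involved
the approximation error is far below measurement noise.

Numerical conventions: fractions outside $[0,1]$ (possible under
measurement noise at small $f_{SIC}$) are clamped to the nearest bound and
flagged, which preserves conservation while keeping the excursions
auditable; end members closer than 5 permil are refused outright because the
inversion variance diverges. The SIC-derived rate is $f \cdot R$ and the
SOC-derived rate is stored as the remainder $R - f R$, with the reported
total defined as their sum so that conservation is bit-exact on every
record.

### Temperature sensitivity

Each source's rates across the 5-30 degC ramp are fitted with the
exponential response $R = B e^{kT}$ and $Q_{10} = e^{10k}$. The default
estimator is ordinary least squares on $\ln R = \ln B + kT$: closed-form,
deterministic, and exact in the noiseless limit. Nonlinear least squares on
the original scale is available (`method = "nls"`) for sensitivity checks;
on noiseless data the two coincide. A fit requires at least 4 strictly
positive points of the 6 nominal temperatures (preserving two residual
degrees of freedom); flat series have undefined log-linear $R^2$ and fail
QC. QC passes when $R^2 > 0.95$ for the SOC-derived series and $R^2 > 0.85$
for the SIC-derived series (the total flux uses the SOC threshold), and QC
failures are excluded from all downstream statistics rather than imputed. A
single $k$ is fitted over the whole ramp; no piecewise Q10.

Two substrate indices accompany the fits: the carbon availability index
(CAI = basal / substrate-induced respiration) and SOC decomposability
($D_{SOC} = B_{SOC}$ / SOC content). SIC content measured as carbonate is
converted with the 0.12 mass proportion of C in CaCO3.

### Gradient statistics

Field-moisture, QC-passed Q10s are regressed on the site aridity index (AI)
per depth and source (OLS slope, Pearson r, two-sided p, 95% CI on the
slope; slopes also reported per 0.1 AI). The moisture-control treatments
(20/40/60% water-holding capacity) are compared with classical two-sided
paired t tests, paired by site, with pairwise deletion per comparison.
Factor correlations (Q10 vs climate, physical, chemical and substrate
variables) are Pearson correlations with, by default, a Holm correction
applied within each response row before the `***`/`**`/`*` coding; the
correction is a flag because different campaigns quote different
conventions, and Holm is the conservative standard choice.

### PCA-composite path analysis

The candidate drivers are grouped as climate (MAT, AI), physical (OC-POM,
OC-MAOM, OC-Fe, OC-Ca), chemical (pH, CEC, Ca, Mg) and substrate (SOC, SIC,
CAI, D_SOC). Each group is reduced to the first principal component of its
correlation matrix (variables standardized; eigenvector sign fixed so the
first listed member loads positively, removing the reflection ambiguity).
The default path diagram sends climate to each soil composite and all four
composites to the response; inter-group arrows among the soil composites
are deliberately omitted, and the diagram is an argument (`default_dag()`)
so any recursive structure can be fitted.

Each structural equation is estimated by least squares on standardized
variables — exactly the maximum-likelihood solution for recursive, fully
observed systems with uncorrelated errors, without iterative optimization.
Effects are decomposed by path tracing computed through powers of the
(nilpotent) coefficient matrix: direct = edge coefficient to the response,
indirect = sum over all other directed paths of coefficient products,
total = direct + indirect, exactly. Fit statistics use the ML discrepancy
$F = \ln|\hat\Sigma| + tr(S\hat\Sigma^{-1}) - \ln|S| - p$ with
$\chi^2 = (n-1)F$, degrees of freedom = distinct moments minus free
parameters, $RMSEA = \sqrt{\max(0, \chi^2 - df)/(df\,(n-1))}$ (zero for a
saturated model), and the standard ML GFI. With the default diagram the
three omitted residual covariances among the soil composites give df = 3;
the composites are deliberately collinear proxies of the same gradient, so
a sizeable $\chi^2$ there is expected and the diagram should be read as an
effect-decomposition device, not as a causal discovery result.

### Dryland bookkeeping

The closing arithmetic chains: dryland heterotrophic respiration = global
soil respiration x dryland share (0.386) x heterotrophic fraction (0.60);
the SIC-derived share of that flux (0.27); the warming-induced increment
$F (Q_{10}^{\Delta T/10} - 1)$ under 4 degC; the percent underestimate when
the SOC-mean Q10 stands in for the SIC-mean Q10; and the offset between the
SOC-flux reduction and SIC-flux gain when the mean Q10s shift by their
per-0.1-AI gradient changes (0.47 down for SOC, 0.39 up for SIC). The
warming-increment functional form is declared (the standard Q10 scaling);
the global-respiration constant (88.0 Pg C yr$^{-1}$) and the mean Q10s
(3.14, 4.23) are back-calculated so the chain reproduces the headline
values 20.4, 3.2 and 4.3 Pg C yr$^{-1}$, and they are labelled as such in
`upscaling_constants()`. The offset ratio is quoted, by default, from
components rounded to one decimal (0.4/1.5 = 26.7%) because that is how the
headline numbers combine; the full-precision chain gives about 24%, and
both are always reported (`rounding = "printed" | "full"`).

```{r upscaling}
up <- run_upscaling()
unlist(up[c("dryland_het_resp", "warming_flux_soc_q10",
            "warming_flux_sic_q10", "underestimate_pct",
            "soc_reduction", "sic_gain", "offset_pct_printed",
            "offset_pct_full")])
```

## The synthetic cohort: what it emulates, and what it does not

The generator (`generate_cohort()`) emulates the study conditions: 30 sites
spanning AI 0.04-0.59 along a dryland transect, MAT in [-1.2, 10.0] degC and
independent of AI, two depths (topsoil 0-10 cm, subsoil 35-50 cm), four
moisture conditions, and one six-temperature incubation series per sample.
Sites are evenly spaced in AI with a small jitter rather than i.i.d.
uniform — mimicking a deliberate transect design and stabilizing slope
recovery across cohorts.

Ground-truth temperature sensitivities are

$$ Q_{10} = \bar Q_{10} + s\,(AI - \overline{AI}) + \text{structured
   deviation} + \epsilon + w \cdot (\text{WHC step}), $$

with $\bar Q_{10}$ = 3.14 (SOC) and 4.23 (SIC), slopes $s$ = +4.7 and -3.9
per AI unit, noise SD 0.25, and WHC increments +0.4 / -0.4 per treatment
step for SOC / SIC. The structured deviation ties Q10_SOC negatively (0.35
per SD) to a latent mineral-protection axis shared with the MAOM-, Fe- and
Ca-bound organic fractions, and Q10_SIC positively (0.35 per SD) to a latent
alkalinity axis shared with pH, cations, CEC and SIC content. Both latents
are independent of AI, so the marginal aridity slopes are exactly the
configured ones; the latents exist because the observed factor-correlation
and path-effect sign patterns (Q10_SOC negatively related to
mineral-protected fractions although positively to AI and OC-POM; Q10_SIC
positively related to pH and cations) cannot arise from a single
AI-driven axis alone. Rate scales are calibrated per sample so the SOC
rate at 20 degC matches the configured depth scale (1.0 / 0.3 ug C g-1 h-1
with log-normal scatter) and the SIC share of the 20 degC flux is exactly
the configured depth contribution (7.2% topsoil, 11.1% subsoil).

Soil properties are linear-in-AI trends plus latent loadings plus Gaussian
noise, with magnitudes chosen once from typical dryland ranges (e.g. pH
7.2-9, SIC up to ~13 g C kg$^{-1}$, SOC 3-14 g C kg$^{-1}$ in topsoil); only
the sign structure is asserted by tests. The forward gas simulation applies
the exact conventions the inversion assumes (same diffusion offset, same
end-member corrections), so with all noise at zero the full pipeline
round-trips every per-sample Q10, B and k to machine precision — that
round-trip, not distributional realism, is what the generator is for.
Measurement noise defaults are 5 ppm on concentrations and 0.15 permil on
delta13C, the precision class of a cavity ring-down gas analyzer.

What the generator does not emulate: spatial autocorrelation, soil-profile
physics, microbial community dynamics, substrate depletion over the ramp,
imperfect flushing, or non-linear property covariance. Passing tests
therefore demonstrate that the estimators are correct and well calibrated
under the stated statistical structure — not that the structure captures
every feature of real dryland soils.

Parameters the data do not pin down and how they were set: the per-site Q10
noise SD (0.25) and measurement noise SDs are calibration choices; the
delta13C end-member means (-24 permil organic, -2 permil carbonate) are
literature-typical values chosen to keep the end members well separated
(they are configuration, not claims); step durations (48-8 h, longer when
cold) sit inside the 4-72 h protocol window; subsoil reuses the topsoil
gradient slopes, as the gradient pattern holds in both layers.

## Design choices that were genuinely open

* **Log-OLS vs NLS for the exponential fit** — log-OLS is the default
  (deterministic, closed-form, exact when noiseless); NLS is a config
  switch. On log-normal multiplicative noise, log-OLS is also the unbiased
  choice for $k$.
* **Estimation of the path model** — per-equation OLS on standardized data
  instead of iterative ML, exact where they coincide (recursive, observed,
  uncorrelated errors). No latent measurement models, modification indices
  or bootstrap standard errors.
* **"Corrected significance" in the correlation table** — implemented as
  Holm per response row, on by default, with a flag to disable; the
  convention is not universal, so it is configuration.
* **Climate composite degeneracy** — MAT and AI are independent by design,
  so the first PC of the climate pair has no stable orientation; its sign
  (and hence the sign of climate's effects) can vary between cohorts. The
  soil-composite effect signs, which are the scientifically interpreted
  ones, are anchored by their latent axes and are stable.
* **Exclusion, not imputation** — QC-failed fits are dropped pairwise per
  analysis (never listwise across sources).

## Problem sizes and determinism

Every stochastic stage draws from a named substream of the master seed
(`stage_seed()`), so cohorts are bit-identical across runs and stages can be
re-run in isolation. The package's own verification uses: one full default
cohort (30 sites x 2 depths x 4 moistures = 240 samples, 1440 incubation
steps) for the calibration and directional checks; 200 field-moisture
cohorts for gradient-slope recovery; 2000 null replicates for the paired-t
size check; 1000 replicates for the $k$-unbiasedness check; exhaustive DAG
enumeration on 3 nodes plus 200 random DAGs on 4-6 nodes for the
effect-decomposition oracle. These sizes were chosen to keep Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

* The aridity slope recovered from fitted Q10s is slightly steeper than the
  generating slope for the SIC source (about -0.42 vs -0.39 per 0.1 AI on
  average): SIC fluxes are small at cold temperatures, so their relative
  measurement noise is aridity-dependent, and the QC filter selects against
  noisy fits preferentially at dry sites. This estimator-level bias is a
  faithful property of the method, inside the stated recovery tolerance; it
  is documented rather than corrected.
* Path-model fit indices on the default cohort are poor by conventional
  SEM standards (RMSEA well above 0.08) because the composites are
  deliberately collinear proxies of one gradient; the model serves effect
  decomposition, not model selection.
* The bookkeeping constants are back-calculations from printed headline
  values, not independent estimates; changing any of them changes all
  downstream numbers, which is why they live in a single config block.
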