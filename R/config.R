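#' Incubation protocol geometry and schedule
#'
#' Describes the closed-jar incubation used throughout: jar volume, soil mass,
#' the bulk density assumed when converting soil mass to occupied volume, the
#' headspace sampling volume, and the per-temperature step durations of the
#' stepwise 5-30 degC ramp.
#'
#' @param jar_volume Jar volume in mL.
#' @param soil_mass_dw Dry-weight soil mass in g.
#' @param assumed_bulk_density Bulk density (g cm^-3) used to compute the
#'   volume occupied by soil, hence the headspace volume.
#' @param sample_volume_removed Headspace gas volume removed per sampling (mL);
#'   replaced with CO2-free air at equal volume.
#' @param flush_to_zero Logical; jars are flushed with CO2-free air before each
#'   step so the initial concentration is 0 ppm.
#' @param pressure Jar pressure in atm.
#' @param temperatures Temperature steps in degC, strictly ascending.
#' @param step_durations Accumulation time in hours for each temperature step;
#'   each must lie in [4, 72] (longer at cold temperatures where fluxes are
#'   small).
#' @return A list of class `incubation_protocol`.
#' @export
incubation_protocol <- function(jar_volume = 250,
                                soil_mass_dw = 50,
                                assumed_bulk_density = 1.3,
                                sample_volume_removed = 15,
                                flush_to_zero = TRUE,
                                pressure = 1.0,
                                temperatures = c(5, 10, 15, 20, 25, 30),
                                step_durations = c(48, 36, 24, 18, 12, 8)) {
  stopifnot(jar_volume > 0, soil_mass_dw >= 0, assumed_bulk_density > 0,
            pressure > 0)
  if (length(step_durations) != length(temperatures)) {
    stop("step_durations must have one entry per temperature")
  }
  if (any(diff(temperatures) <= 0)) {
    stop("protocol temperatures must be strictly ascending")
  }
  if (any(step_durations < 4 | step_durations > 72)) {
    stop("step durations must lie within [4, 72] hours")
  }
  structure(list(
    jar_volume = jar_volume,
    soil_mass_dw = soil_mass_dw,
    assumed_bulk_density = assumed_bulk_density,
    sample_volume_removed = sample_volume_removed,
    flush_to_zero = flush_to_zero,
    pressure = pressure,
    temperatures = temperatures,
    step_durations = step_durations
  ), class = "incubation_protocol")
}

#' delta13C end-member correction settings
#'
#' The mixing model compares the delta13C of soil CO2 against the SOC and SIC
#' end members. Emitted CO2 is depleted relative to soil CO2 by a constant
#' diffusion fractionation (default 4.4 permil), and end members may receive a
#' linear temperature-dependent fractionation correction `a + b * T` (default
#' off: the delta13C of a source and of its CO2 are taken as equal).
#'
#' @param diffusion_offset Permil by which emitted CO2 is lower than soil CO2.
#' @param temp_fractionation_coeffs Numeric `c(a, b)`: permil offset and permil
#'   per degC applied to end members. Default `c(0, 0)` (no-op).
#' @param min_separation Minimum |delta_SIC - delta_SOC| (permil) below which
#'   partitioning is refused as ill-conditioned.
#' @return A list of class `end_members_config`.
#' @export
end_members_config <- function(diffusion_offset = 4.4,
                               temp_fractionation_coeffs = c(0, 0),
                               min_separation = 5) {
  stopifnot(is.finite(diffusion_offset),
            length(temp_fractionation_coeffs) == 2,
            all(is.finite(temp_fractionation_coeffs)),
            min_separation > 0)
  structure(list(
    diffusion_offset = diffusion_offset,
    temp_fractionation_coeffs = temp_fractionation_coeffs,
    min_separation = min_separation
  ), class = "end_members_config")
}

#' Synthetic cohort generator configuration
#'
#' Defines the study conditions the generator emulates: a 30-site dryland
#' transect spanning aridity index (AI) 0.04-0.59, two depths, four moisture
#' conditions, and per-sample exponential temperature responses of SOC- and
#' SIC-derived CO2 whose Q10 values trend with aridity in opposite directions
#' (Q10_SOC increases, Q10_SIC decreases with AI).
#'
#' Ground-truth Q10s are built as
#' `q10_mean + slope * (AI - mean AI) + structured deviation + noise`,
#' plus `whc_effect * (level index - 1)` for the water-holding-capacity
#' treatments. The structured deviation couples Q10_SOC (negatively) to a
#' latent mineral-protection axis shared with the MAOM/Fe/Ca-bound organic
#' fractions, and Q10_SIC (positively) to a latent alkalinity axis shared
#' with pH, cations, CEC and SIC content; both latents are independent of AI,
#' so marginal aridity slopes are untouched.
#'
#' @param n_sites Number of transect sites (>= 3).
#' @param ai_range Aridity index interval, within [0, 1].
#' @param mat_range Mean annual temperature interval (degC).
#' @param depths Depth labels.
#' @param moisture_levels Moisture conditions; `"field"` plus WHC treatments.
#' @param q10_soc_slope,q10_sic_slope Q10 change per unit AI.
#' @param q10_soc_mean,q10_sic_mean Cohort-mean Q10 at field moisture.
#' @param q10_noise_sd SD of the unstructured Q10 noise.
#' @param q10_protection_effect Q10_SOC decrement per SD of the latent
#'   mineral-protection deviation.
#' @param q10_alkalinity_effect Q10_SIC increment per SD of the latent
#'   alkalinity deviation.
#' @param sic_contribution_20C Named fractions: true SIC share of the total
#'   flux at 20 degC for each depth.
#' @param r_soc_20C Named rates (ug C g^-1 h^-1): SOC-derived flux at 20 degC
#'   for each depth.
#' @param rate_log_sd SD of the per-sample log-normal scatter on the 20 degC
#'   SOC rate.
#' @param delta13c_soc_mean,delta13c_soc_sd,delta13c_sic_mean,delta13c_sic_sd
#'   End-member delta13C distributions (permil VPDB).
#' @param whc_effect_soc,whc_effect_sic Q10 increment per WHC treatment step
#'   (20 -> 40 -> 60% WHC); opposite signs for the two sources.
#' @param co2_noise_sd Measurement noise SD on final CO2 concentration (ppm).
#' @param delta13c_noise_sd Measurement noise SD on headspace delta13C
#'   (permil).
#' @param protocol An [incubation_protocol()].
#' @param end_members An [end_members_config()].
#' @param seed Integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_sites = 30,
                          ai_range = c(0.04, 0.59),
                          mat_range = c(-1.2, 10.0),
                          depths = c("topsoil", "subsoil"),
                          moisture_levels = c("field", "WHC20", "WHC40", "WHC60"),
                          q10_soc_slope = 4.7,
                          q10_sic_slope = -3.9,
                          q10_soc_mean = 3.14,
                          q10_sic_mean = 4.23,
                          q10_noise_sd = 0.25,
                          q10_protection_effect = 0.35,
                          q10_alkalinity_effect = 0.35,
                          sic_contribution_20C = c(topsoil = 0.072, subsoil = 0.111),
                          r_soc_20C = c(topsoil = 1.0, subsoil = 0.3),
                          rate_log_sd = 0.3,
                          delta13c_soc_mean = -24, delta13c_soc_sd = 1,
                          delta13c_sic_mean = -2, delta13c_sic_sd = 1,
                          whc_effect_soc = 0.4,
                          whc_effect_sic = -0.4,
                          co2_noise_sd = 5,
                          delta13c_noise_sd = 0.15,
                          protocol = incubation_protocol(),
                          end_members = end_members_config(),
                          seed = 1L) {
  stopifnot(ai_range[1] >= 0, ai_range[2] <= 1, ai_range[1] < ai_range[2],
            mat_range[1] < mat_range[2],
            all(r_soc_20C > 0), rate_log_sd >= 0,
            all(sic_contribution_20C > 0), all(sic_contribution_20C < 1),
            is.finite(q10_soc_slope), is.finite(q10_sic_slope),
            q10_noise_sd >= 0, co2_noise_sd >= 0, delta13c_noise_sd >= 0)
  if (n_sites < 3) stop("n_sites must be >= 3 (regression stages undefined)")
  if (length(moisture_levels) == 0) stop("moisture_levels must be non-empty")
  if (!all(depths %in% names(sic_contribution_20C)) ||
      !all(depths %in% names(r_soc_20C))) {
    stop("sic_contribution_20C and r_soc_20C must be named for every depth")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Derive a reproducible per-stage seed from the master seed. Kept below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(stage))) %%
               .Machine$integer.max)
}
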