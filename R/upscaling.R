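#' Constants for the dryland carbon bookkeeping
#'
#' All quantities used by the upscaling arithmetic live here; nothing is
#' hard-coded in the operations. The global soil respiration default (88.0
#' Pg C yr^-1) is back-calculated so that dryland share x heterotrophic
#' fraction reproduces the 20.4 Pg C yr^-1 dryland heterotrophic flux; the
#' mean Q10 defaults (3.14 and 4.23) are back-calculated from the 3.2 and
#' 4.3 Pg C yr^-1 warming increments under 4 degC with the SIC base flux
#' 20.4 x 0.27 (see the methods vignette for the derivation).
#'
#' @param rs_global Global soil respiration (Pg C yr^-1).
#' @param dryland_share Dryland share of global soil respiration.
#' @param heterotrophic_fraction Heterotrophic share of dryland respiration.
#' @param sic_share SIC-derived share of dryland heterotrophic CO2.
#' @param delta_t Warming scenario (degC).
#' @param mean_q10_soc,mean_q10_sic Cohort-mean temperature sensitivities.
#' @param q10_soc_change_per_0p1_ai Q10_SOC decrease per 0.1 decrease in
#'   aridity index.
#' @param q10_sic_change_per_0p1_ai Q10_SIC increase per 0.1 decrease in
#'   aridity index.
#' @return A list of class `upscaling_constants`.
#' @export
upscaling_constants <- function(rs_global = 88.0,
                                dryland_share = 0.386,
                                heterotrophic_fraction = 0.60,
                                sic_share = 0.27,
                                delta_t = 4.0,
                                mean_q10_soc = 3.14,
                                mean_q10_sic = 4.23,
                                q10_soc_change_per_0p1_ai = 0.47,
                                q10_sic_change_per_0p1_ai = 0.39) {
  fracs <- c(dryland_share, heterotrophic_fraction, sic_share)
  stopifnot(all(fracs > 0), all(fracs < 1), rs_global >= 0,
            mean_q10_soc > 1, mean_q10_sic > 1)
  structure(as.list(environment())[c(
    "rs_global", "dryland_share", "heterotrophic_fraction", "sic_share",
    "delta_t", "mean_q10_soc", "mean_q10_sic",
    "q10_soc_change_per_0p1_ai", "q10_sic_change_per_0p1_ai")],
    class = "upscaling_constants")
}

#' Dryland heterotrophic respiration
#'
#' `rs_global x dryland_share x heterotrophic_fraction` (Pg C yr^-1).
#'
#' @param constants An [upscaling_constants()].
#' @return Pg C yr^-1.
#' @export
dryland_heterotrophic_respiration <- function(constants = upscaling_constants()) {
  constants$rs_global * constants$dryland_share *
    constants$heterotrophic_fraction
}

#' Warming-induced flux increment
#'
#' Q10 scaling of a baseline flux: the increment above baseline under
#' `delta_t` degC of warming is `base_flux x (q10^(delta_t / 10) - 1)`.
#'
#' @param base_flux Baseline flux (Pg C yr^-1), >= 0.
#' @param q10 Temperature sensitivity, > 0.
#' @param delta_t Warming (degC).
#' @return Flux increment (Pg C yr^-1).
#' @export
warming_induced_flux <- function(base_flux, q10, delta_t = 4.0) {
  stopifnot(all(base_flux >= 0), all(q10 > 0))
  base_flux * (q10^(delta_t / 10) - 1)
}

#' Relative underestimate between two flux estimates
#'
#' `100 x (1 - flux_low / flux_high)` percent.
#'
#' @param flux_low,flux_high Fluxes; `flux_high` must be > 0.
#' @return Percent.
#' @export
underestimate_percent <- function(flux_low, flux_high) {
  if (any(flux_high <= 0)) stop("flux_high must be > 0")
  100 * (1 - flux_low / flux_high)
}

#' Aridity-driven offset between SOC reduction and SIC gain
#'
#' Under a 0.1 decrease in aridity index, Q10_SOC drops by the configured
#' change and Q10_SIC rises by its change. The SOC warming increment shrinks
#' (`soc_reduction = old - new`) while the SIC increment grows
#' (`sic_gain = new - old`); the offset is `100 x sic_gain / soc_reduction`.
#' With `rounding = "printed"` both components are rounded to one decimal
#' before the ratio (0.4 / 1.5 -> 26.7%), matching how the headline numbers
#' are quoted; `"full"` keeps full precision (about 24%). Both are reported.
#'
#' @param constants An [upscaling_constants()].
#' @param rounding `"printed"` (default) or `"full"`.
#' @return A list: `soc_reduction`, `sic_gain` (full precision),
#'   `soc_reduction_rounded`, `sic_gain_rounded`, `offset_pct` (per the
#'   chosen rounding), `offset_pct_printed`, `offset_pct_full`.
#' @export
aridity_offset <- function(constants = upscaling_constants(),
                           rounding = c("printed", "full")) {
  rounding <- match.arg(rounding)
  het <- dryland_heterotrophic_respiration(constants)
  base_sic <- het * constants$sic_share
  base_soc <- het * (1 - constants$sic_share)
  soc_old <- warming_induced_flux(base_soc, constants$mean_q10_soc,
                                  constants$delta_t)
  soc_new <- warming_induced_flux(
    base_soc, constants$mean_q10_soc - constants$q10_soc_change_per_0p1_ai,
    constants$delta_t)
  sic_old <- warming_induced_flux(base_sic, constants$mean_q10_sic,
                                  constants$delta_t)
  sic_new <- warming_induced_flux(
    base_sic, constants$mean_q10_sic + constants$q10_sic_change_per_0p1_ai,
    constants$delta_t)
  soc_reduction <- soc_old - soc_new
  sic_gain <- sic_new - sic_old
  if (soc_reduction <= 0) stop("SOC reduction is not positive; no offset defined")
  sr <- round(soc_reduction, 1)
  sg <- round(sic_gain, 1)
  if (sr <= 0) stop("rounded SOC reduction is zero; no offset defined")
  offset_printed <- 100 * sg / sr
  offset_full <- 100 * sic_gain / soc_reduction
  list(soc_reduction = soc_reduction, sic_gain = sic_gain,
       soc_reduction_rounded = sr, sic_gain_rounded = sg,
       offset_pct = if (rounding == "printed") offset_printed else offset_full,
       offset_pct_printed = offset_printed, offset_pct_full = offset_full)
}

#' Full dryland upscaling bookkeeping
#'
#' Chains the heterotrophic-respiration estimate, the warming-induced
#' SIC-derived flux under the SOC-mean and SIC-mean Q10s, the resulting
#' underestimate, and the aridity offset.
#'
#' @param constants An [upscaling_constants()].
#' @param rounding Passed to [aridity_offset()].
#' @return A list with every intermediate value.
#' @export
run_upscaling <- function(constants = upscaling_constants(),
                          rounding = "printed") {
  het <- dryland_heterotrophic_respiration(constants)
  base_sic <- het * constants$sic_share
  base_soc <- het * (1 - constants$sic_share)
  flux_soc_q10 <- warming_induced_flux(base_sic, constants$mean_q10_soc,
                                       constants$delta_t)
  flux_sic_q10 <- warming_induced_flux(base_sic, constants$mean_q10_sic,
                                       constants$delta_t)
  off <- aridity_offset(constants, rounding)
  list(
    dryland_het_resp = het,
    f_sic_base = base_sic,
    f_soc_base = base_soc,
    warming_flux_soc_q10 = flux_soc_q10,
    warming_flux_sic_q10 = flux_sic_q10,
    underestimate_pct = underestimate_percent(flux_soc_q10, flux_sic_q10),
    soc_reduction = off$soc_reduction,
    sic_gain = off$sic_gain,
    offset_pct = off$offset_pct,
    offset_pct_printed = off$offset_pct_printed,
    offset_pct_full = off$offset_pct_full,
    constants = constants
  )
}
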