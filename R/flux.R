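#' Ideal-gas molar volume at jar temperature
#'
#' `22.414 * (T + 273.15) / 273.15` L mol^-1 at 1 atm.
#'
#' @param temperature Temperature in degC.
#' @return Molar volume in L mol^-1.
#' @export
molar_volume <- function(temperature) {
  22.414 * (temperature + 273.15) / 273.15
}

#' Jar headspace volume
#'
#' Jar volume minus the volume occupied by the soil (mass over assumed bulk
#' density), in litres.
#'
#' @param protocol An [incubation_protocol()].
#' @return Headspace volume in L.
#' @export
headspace_volume <- function(protocol) {
  stopifnot(protocol$assumed_bulk_density > 0)
  v_ml <- protocol$jar_volume -
    protocol$soil_mass_dw / protocol$assumed_bulk_density
  if (v_ml <= 0) stop("soil volume fills or exceeds the jar: headspace <= 0")
  v_ml / 1000
}

#' Emission rate from a closed-jar accumulation step
#'
#' Standard closed-chamber arithmetic: the headspace concentration increase
#' over the step, converted through the ideal-gas molar volume at the
#' incubation temperature, gives mass of C per gram of soil per hour:
#' `rate = dC * 1e-6 * V_head / Vm(T) * 12.011e6 / (mass * duration)`.
#' The delta13C of emitted CO2 comes from a two-point isotope mass balance,
#' which reduces to the headspace delta13C when the jar was flushed
#' (`co2_initial = 0`).
#'
#' Negative concentration differences are retained (never clipped) and flagged
#' via `qc_negative`; the fitting stage excludes them by its point-count rule.
#'
#' @param step Data frame (one or more rows) with `sample_id`, `temperature`,
#'   `duration`, `co2_initial`, `co2_final`, `delta13c_headspace` and
#'   optionally `delta13c_initial`.
#' @param protocol An [incubation_protocol()].
#' @return A tibble with `rate_total` (ug C g^-1 h^-1), `delta13c_emitted`,
#'   and `qc_negative`.
#' @export
emission_rate <- function(step, protocol = incubation_protocol()) {
  if (any(step$duration <= 0)) stop("duration must be > 0")
  if (any(step$co2_initial < 0 | step$co2_final < 0)) {
    stop("concentrations must be >= 0")
  }
  v_head <- headspace_volume(protocol)
  d_ppm <- step$co2_final - step$co2_initial
  rate <- d_ppm * 1e-6 * v_head / molar_volume(step$temperature) *
    protocol$pressure * 12.011e6 /
    (protocol$soil_mass_dw * step$duration)
  d_init <- if ("delta13c_initial" %in% names(step)) {
    step$delta13c_initial
  } else {
    rep(NA_real_, nrow(step))
  }
  # two-point mass balance; with a flushed jar the emitted CO2 is all of the
  # final headspace CO2
  d_emit <- ifelse(step$co2_initial == 0 | is.na(d_init),
                   step$delta13c_headspace,
                   (step$co2_final * step$delta13c_headspace -
                      step$co2_initial * d_init) / d_ppm)
  tibble::tibble(
    sample_id = step$sample_id,
    temperature = step$temperature,
    rate_total = rate,
    delta13c_emitted = d_emit,
    qc_negative = d_ppm < 0
  )
}

#' Emission rates for a whole incubation table
#'
#' @param incubation Incubation steps, as produced by [generate_cohort()] or
#'   read from `incubation.csv`.
#' @param protocol An [incubation_protocol()].
#' @return One emission-rate row per incubation step.
#' @export
compute_fluxes <- function(incubation, protocol = incubation_protocol()) {
  emission_rate(incubation, protocol)
}
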