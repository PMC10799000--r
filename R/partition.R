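#' Diffusion correction of emitted delta13C
#'
#' CO2 leaving the soil is depleted relative to soil CO2 by a constant
#' fractionation induced by molecular diffusion; adding the offset (default
#' 4.4 permil) recovers the delta13C of soil CO2 from the emitted value.
#'
#' @param delta_emitted delta13C of emitted CO2 (permil VPDB).
#' @param offset Diffusion fractionation (permil).
#' @return delta13C of soil CO2 (permil).
#' @export
correct_diffusion <- function(delta_emitted, offset = 4.4) {
  stopifnot(all(is.finite(delta_emitted)), is.finite(offset))
  delta_emitted + offset
}

#' Temperature-dependent fractionation correction of an end member
#'
#' Linear hook `delta + a + b * T`; the default coefficients `(0, 0)` make it
#' a no-op, i.e. the delta13C of a source and of its CO2 are assumed equal.
#'
#' @param delta_end End-member delta13C (permil).
#' @param temperature Temperature (degC).
#' @param coeffs Numeric `c(a, b)` in permil and permil per degC.
#' @return Corrected end-member delta13C.
#' @export
correct_temperature_fractionation <- function(delta_end, temperature,
                                              coeffs = c(0, 0)) {
  stopifnot(all(is.finite(coeffs)))
  delta_end + coeffs[1] + coeffs[2] * temperature
}

#' Two-end-member mixing fraction
#'
#' Inverts the linear mixing model
#' `delta_total = (1 - f) * delta_SOC + f * delta_SIC` for the SIC-derived
#' fraction `f = (delta_total - delta_SOC) / (delta_SIC - delta_SOC)`. Values
#' outside `[0, 1]` (measurement-noise excursions) are clamped to the nearest
#' bound and flagged.
#'
#' @param delta_total delta13C of the mixture (soil CO2, permil).
#' @param delta_soc_end,delta_sic_end End-member delta13C values (permil).
#' @param min_separation Minimum |delta_SIC - delta_SOC| accepted.
#' @return A list with `f_sic` and logical `clamped`, each the length of
#'   `delta_total`.
#' @export
partition_fraction <- function(delta_total, delta_soc_end, delta_sic_end,
                               min_separation = 5) {
  sep <- abs(delta_sic_end - delta_soc_end)
  if (any(sep < min_separation)) {
    stop(sprintf(
      "end members separated by less than %g permil: mixing ill-conditioned",
      min_separation))
  }
  f <- (delta_total - delta_soc_end) / (delta_sic_end - delta_soc_end)
  clamped <- f < 0 | f > 1
  list(f_sic = clampv(f, 0, 1), clamped = clamped)
}

#' Partition emission rates into SOC- and SIC-derived components
#'
#' Applies the diffusion correction to the emitted delta13C, the temperature
#' fractionation correction to both end members, solves the mixing model for
#' `f_SIC`, and splits the total rate: `r_sic = f * rate_total`,
#' `r_soc = (1 - f) * rate_total`, so the two components sum to the total
#' exactly on every record.
#'
#' @param rate Emission-rate rows from [emission_rate()] (needs `rate_total`,
#'   `delta13c_emitted`, `temperature`).
#' @param delta13c_soc_end,delta13c_sic_end Per-row end-member delta13C.
#' @param ends An [end_members_config()].
#' @return A tibble with `f_sic`, `r_soc`, `r_sic`, `clamped`.
#' @export
partition_rates <- function(rate, delta13c_soc_end, delta13c_sic_end,
                            ends = end_members_config()) {
  d_soil <- correct_diffusion(rate$delta13c_emitted, ends$diffusion_offset)
  d_soc <- correct_temperature_fractionation(delta13c_soc_end,
                                             rate$temperature,
                                             ends$temp_fractionation_coeffs)
  d_sic <- correct_temperature_fractionation(delta13c_sic_end,
                                             rate$temperature,
                                             ends$temp_fractionation_coeffs)
  pf <- partition_fraction(d_soil, d_soc, d_sic, ends$min_separation)
  r_sic <- pf$f_sic * rate$rate_total
  r_soc <- rate$rate_total - r_sic
  tibble::tibble(
    sample_id = rate$sample_id,
    temperature = rate$temperature,
    # the reported total is the component sum (conservation bit-exact; it can
    # differ from the measured total by at most one ulp)
    rate_total = r_soc + r_sic,
    f_sic = pf$f_sic,
    r_soc = r_soc,
    r_sic = r_sic,
    clamped = pf$clamped,
    qc_negative = if ("qc_negative" %in% names(rate)) rate$qc_negative
                  else rate$rate_total < 0
  )
}

#' Partition a whole cohort's fluxes
#'
#' Joins each emission record to its sample's end members and applies
#' [partition_rates()].
#'
#' @param emissions Output of [compute_fluxes()].
#' @param samples Sample table with `sample_id`, `delta13c_soc`,
#'   `delta13c_sic`.
#' @param ends An [end_members_config()].
#' @return Partition table, one row per emission record.
#' @export
partition_all <- function(emissions, samples, ends = end_members_config()) {
  em <- dplyr::inner_join(
    emissions,
    samples[, c("sample_id", "delta13c_soc", "delta13c_sic")],
    by = "sample_id")
  if (nrow(em) != nrow(emissions)) {
    stop("some emission records have no matching sample end members")
  }
  partition_rates(em, em$delta13c_soc, em$delta13c_sic, ends)
}
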