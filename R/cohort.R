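#' @importFrom stats rnorm runif lm coef pchisq pt qt sd var cor cor.test
#'   t.test setNames complete.cases cov p.adjust lm.fit nls
#' @importFrom utils head
NULL

# Per-depth linear-in-AI soil property model: value = base + slope * z +
# u_load * latent + noise_sd * eps, where z = AI - cohort-mean AI. Latent "P"
# is the mineral-protection axis (MAOM/Fe/Ca-bound fractions), latent "C" is
# the carbonate/alkalinity axis (pH, cations, CEC, SIC). Magnitudes are
# calibration choices sized to dryland literature ranges; only the signs are
# asserted downstream.
soil_property_params <- function(depth) {
  if (depth == "topsoil") {
    list(
      ph      = list(base = 8.2, slope = -1.8, latent = "C", load = 0.35, sd = 0.12, min = 4,    max = 11),
      cec     = list(base = 14,  slope = -6.0, latent = "C", load = 1.50, sd = 1.20, min = 1,    max = Inf),
      ca      = list(base = 3.0, slope = -2.5, latent = "C", load = 0.80, sd = 0.30, min = 0.05, max = Inf),
      mg      = list(base = 1.2, slope = -0.9, latent = "C", load = 0.30, sd = 0.15, min = 0.02, max = Inf),
      sic     = list(base = 8.0, slope = -9.0, latent = "C", load = 1.20, sd = 1.00, min = 0.10, max = Inf),
      soc     = list(base = 8.0, slope = 18.0, latent = NA,  load = 0,    sd = 1.00, min = 0.50, max = Inf),
      oc_pom  = list(base = 2.0, slope =  4.0, latent = "P", load = 0.20, sd = 0.30, min = 0.05, max = Inf),
      oc_maom = list(base = 6.0, slope =  0.8, latent = "P", load = 2.00, sd = 0.30, min = 0.10, max = Inf),
      oc_fe   = list(base = 1.2, slope =  0.8, latent = "P", load = 0.80, sd = 0.15, min = 0.02, max = Inf),
      oc_ca   = list(base = 2.0, slope =  1.0, latent = "P", load = 1.00, sd = 0.20, min = 0.02, max = Inf),
      cai     = list(base = 0.15, slope = 0.25, latent = NA, load = 0,    sd = 0.03, min = 0.01, max = 0.95)
    )
  } else {
    list(
      ph      = list(base = 8.4, slope = -1.6, latent = "C", load = 0.35, sd = 0.12, min = 4,    max = 11),
      cec     = list(base = 12,  slope = -5.0, latent = "C", load = 1.30, sd = 1.00, min = 1,    max = Inf),
      ca      = list(base = 3.6, slope = -2.5, latent = "C", load = 0.80, sd = 0.30, min = 0.05, max = Inf),
      mg      = list(base = 1.4, slope = -0.9, latent = "C", load = 0.30, sd = 0.15, min = 0.02, max = Inf),
      sic     = list(base = 10.0, slope = -9.0, latent = "C", load = 1.20, sd = 1.00, min = 0.10, max = Inf),
      soc     = list(base = 3.5, slope =  7.0, latent = NA,  load = 0,    sd = 0.60, min = 0.30, max = Inf),
      oc_pom  = list(base = 0.7, slope =  1.4, latent = "P", load = 0.10, sd = 0.15, min = 0.02, max = Inf),
      oc_maom = list(base = 2.8, slope =  0.4, latent = "P", load = 1.00, sd = 0.20, min = 0.05, max = Inf),
      oc_fe   = list(base = 0.6, slope =  0.4, latent = "P", load = 0.40, sd = 0.10, min = 0.01, max = Inf),
      oc_ca   = list(base = 1.0, slope =  0.5, latent = "P", load = 0.50, sd = 0.12, min = 0.01, max = Inf),
      cai     = list(base = 0.12, slope = 0.20, latent = NA, load = 0,    sd = 0.03, min = 0.01, max = 0.95)
    )
  }
}

clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a complete synthetic study cohort
#'
#' Draws sites along the aridity gradient (evenly spaced AI plus a small
#' jitter, mimicking a deliberate transect design), per site x depth soil
#' properties with the configured aridity trends, per site x depth x moisture
#' ground-truth temperature responses, and the forward-simulated incubation
#' gas series for every sample. All randomness derives from `config$seed`
#' through named stage substreams, so identical seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `sites`, `samples`, `incubation`, and `truth`
#'   (generator ground truth, kept separate so the analysis-facing tables look
#'   like real study inputs).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sites <- generate_sites(config)
  samples <- generate_samples(config, sites)
  incubation <- synthesize_cohort_incubation(config, samples)
  truth_cols <- c("sample_id", "site_id", "depth", "moisture",
                  "true_q10_soc", "true_q10_sic", "true_k_soc", "true_k_sic",
                  "true_b_soc", "true_b_sic", "true_f_sic_20C")
  truth <- samples[truth_cols]
  samples <- samples[setdiff(names(samples),
                             setdiff(truth_cols,
                                     c("sample_id", "site_id", "depth", "moisture")))]
  list(sites = sites, samples = samples, incubation = incubation,
       truth = truth, config = config)
}

generate_sites <- function(config) {
  n <- config$n_sites
  set.seed(stage_seed(config$seed, "sites"))
  spacing <- diff(config$ai_range) / (n - 1)
  ai <- seq(config$ai_range[1], config$ai_range[2], length.out = n) +
    runif(n, -0.3, 0.3) * spacing
  ai <- clampv(ai, config$ai_range[1], config$ai_range[2])
  mat <- runif(n, config$mat_range[1], config$mat_range[2])
  map <- clampv(46 + 800 * (ai - config$ai_range[1]) + rnorm(n, 0, 25), 20, 600)
  tibble::tibble(
    site_id = sprintf("S%02d", seq_len(n)),
    aridity_index = ai,
    mat = mat,
    map = map,
    longitude = sort(runif(n, 81.02, 123.53))
  )
}

generate_samples <- function(config, sites) {
  set.seed(stage_seed(config$seed, "samples"))
  z_all <- sites$aridity_index - mean(sites$aridity_index)
  per_depth <- lapply(config$depths, function(depth) {
    pp <- soil_property_params(depth)
    n <- nrow(sites)
    u_p <- rnorm(n)   # latent mineral-protection deviation
    u_c <- rnorm(n)   # latent alkalinity/carbonate deviation
    props <- lapply(pp, function(p) {
      u <- switch(as.character(p$latent), P = u_p, C = u_c, rep(0, n))
      clampv(p$base + p$slope * z_all + p$load * u + rnorm(n, 0, p$sd),
             p$min, p$max)
    })
    df <- tibble::as_tibble(props)
    df$site_id <- sites$site_id
    df$depth <- depth
    df$u_p <- u_p
    df$u_c <- u_c
    df$z <- z_all
    # substrate-induced respiration scales with SOC; basal = CAI * SIR so the
    # availability index is recovered exactly by the ratio
    df$sir_resp <- pmax(0.08 * df$soc + rnorm(n, 0, 0.05), 0.02)
    df$basal_resp <- df$cai * df$sir_resp
    df$delta13c_soc <- rnorm(n, config$delta13c_soc_mean, config$delta13c_soc_sd)
    df$delta13c_sic <- rnorm(n, config$delta13c_sic_mean, config$delta13c_sic_sd)
    df$r20_soc <- config$r_soc_20C[[depth]] * exp(rnorm(n, 0, config$rate_log_sd))
    df
  })
  soils <- dplyr::bind_rows(per_depth)

  # expand to moisture treatments; soil properties are those of the same soil
  grid <- expand.grid(moisture = config$moisture_levels,
                      depth = config$depths,
                      site_id = sites$site_id,
                      stringsAsFactors = FALSE)
  samples <- dplyr::inner_join(tibble::as_tibble(grid), soils,
                               by = c("site_id", "depth"))

  # ground-truth temperature responses
  whc_idx <- match(samples$moisture, c("WHC20", "WHC40", "WHC60"))
  whc_step <- ifelse(is.na(whc_idx), 0, whc_idx - 1)
  n_s <- nrow(samples)
  q10_soc <- config$q10_soc_mean + config$q10_soc_slope * samples$z -
    config$q10_protection_effect * samples$u_p +
    config$whc_effect_soc * whc_step + rnorm(n_s, 0, config$q10_noise_sd)
  q10_sic <- config$q10_sic_mean + config$q10_sic_slope * samples$z +
    config$q10_alkalinity_effect * samples$u_c +
    config$whc_effect_sic * whc_step + rnorm(n_s, 0, config$q10_noise_sd)
  samples$true_q10_soc <- pmax(q10_soc, 1.05)
  samples$true_q10_sic <- pmax(q10_sic, 1.05)
  samples$true_k_soc <- log(samples$true_q10_soc) / 10
  samples$true_k_sic <- log(samples$true_q10_sic) / 10
  # B calibrated so r_soc(20) = r20 and r_sic(20)/(r_soc+r_sic)(20) = c(depth)
  cc <- unname(config$sic_contribution_20C[samples$depth])
  samples$true_b_soc <- samples$r20_soc * exp(-20 * samples$true_k_soc)
  samples$true_b_sic <- samples$r20_soc * cc / (1 - cc) *
    exp(-20 * samples$true_k_sic)
  samples$true_f_sic_20C <- cc
  samples$sample_id <- sprintf("%s_%s_%s", samples$site_id, samples$depth,
                               samples$moisture)
  samples$z <- samples$u_p <- samples$u_c <- samples$r20_soc <- NULL
  samples$cai <- NULL  # derivable exactly as basal_resp / sir_resp
  front <- c("sample_id", "site_id", "depth", "moisture")
  samples[c(front, setdiff(names(samples), front))]
}

#' Ground-truth source emission rates at a temperature
#'
#' Forward model `R = B * exp(k * T)` for each source, using the generator's
#' per-sample ground-truth parameters.
#'
#' @param sample One-row data frame (or list) with `true_b_soc`, `true_k_soc`,
#'   `true_b_sic`, `true_k_sic`; vectorized over rows.
#' @param temperature Temperature in degC.
#' @return A list with numeric `r_soc` and `r_sic` (ug C g^-1 h^-1).
#' @export
source_rates <- function(sample, temperature) {
  need <- c("true_b_soc", "true_k_soc", "true_b_sic", "true_k_sic")
  if (!all(need %in% names(sample))) {
    stop("sample lacks ground-truth parameters: ",
         paste(setdiff(need, names(sample)), collapse = ", "))
  }
  list(r_soc = sample$true_b_soc * exp(sample$true_k_soc * temperature),
       r_sic = sample$true_b_sic * exp(sample$true_k_sic * temperature))
}

#' Forward-simulate one sample's incubation series
#'
#' For each protocol temperature, accumulates headspace CO2 from the
#' ground-truth source rates over the step duration, mixes the two sources'
#' delta13C using exactly the conventions the inversion assumes (end members
#' shifted by the temperature fractionation, then the mixture depleted by the
#' diffusion offset), and adds measurement noise. Jars are flushed to 0 ppm
#' before each step.
#'
#' @param sample One-row sample data frame with ground-truth fields and
#'   end-member delta13C values.
#' @param config A [cohort_config()] (noise and corrections).
#' @param protocol An [incubation_protocol()].
#' @return A tibble of incubation steps.
#' @export
synthesize_incubation <- function(sample, config, protocol = config$protocol) {
  if (any(protocol$step_durations <= 0)) stop("non-positive step duration")
  temps <- protocol$temperatures
  rates <- source_rates(sample, temps)
  r_tot <- rates$r_soc + rates$r_sic
  f_sic <- ifelse(r_tot > 0, rates$r_sic / r_tot, 0)
  v_head <- headspace_volume(protocol)
  mass_c <- r_tot * protocol$soil_mass_dw * protocol$step_durations   # ug C
  d_ppm <- mass_c / 12.011 * molar_volume(temps) / v_head / protocol$pressure
  a <- config$end_members$temp_fractionation_coeffs[1]
  b <- config$end_members$temp_fractionation_coeffs[2]
  d_soc_end <- sample$delta13c_soc + a + b * temps
  d_sic_end <- sample$delta13c_sic + a + b * temps
  d_head <- (1 - f_sic) * d_soc_end + f_sic * d_sic_end -
    config$end_members$diffusion_offset
  n <- length(temps)
  tibble::tibble(
    sample_id = sample$sample_id,
    temperature = temps,
    duration = protocol$step_durations,
    co2_initial = rep(0, n),
    co2_final = pmax(d_ppm + rnorm(n, 0, config$co2_noise_sd), 0),
    delta13c_headspace = d_head + rnorm(n, 0, config$delta13c_noise_sd)
  )
}

# vectorized forward simulation for the whole cohort (one rnorm stream)
synthesize_cohort_incubation <- function(config, samples) {
  set.seed(stage_seed(config$seed, "incubation"))
  protocol <- config$protocol
  temps <- protocol$temperatures
  nt <- length(temps)
  ns <- nrow(samples)
  idx <- rep(seq_len(ns), each = nt)
  tt <- rep(temps, times = ns)
  dur <- rep(protocol$step_durations, times = ns)
  r_soc <- samples$true_b_soc[idx] * exp(samples$true_k_soc[idx] * tt)
  r_sic <- samples$true_b_sic[idx] * exp(samples$true_k_sic[idx] * tt)
  r_tot <- r_soc + r_sic
  f_sic <- ifelse(r_tot > 0, r_sic / r_tot, 0)
  v_head <- headspace_volume(protocol)
  d_ppm <- r_tot * protocol$soil_mass_dw * dur / 12.011 *
    molar_volume(tt) / v_head / protocol$pressure
  a <- config$end_members$temp_fractionation_coeffs[1]
  b <- config$end_members$temp_fractionation_coeffs[2]
  d_head <- (1 - f_sic) * (samples$delta13c_soc[idx] + a + b * tt) +
    f_sic * (samples$delta13c_sic[idx] + a + b * tt) -
    config$end_members$diffusion_offset
  tibble::tibble(
    sample_id = samples$sample_id[idx],
    temperature = tt,
    duration = dur,
    co2_initial = 0,
    co2_final = pmax(d_ppm + rnorm(ns * nt, 0, config$co2_noise_sd), 0),
    delta13c_headspace = d_head + rnorm(ns * nt, 0, config$delta13c_noise_sd)
  )
}

#' Noise-free generator configuration
#'
#' Convenience wrapper: a [cohort_config()] with every stochastic term of the
#' ground truth and the measurements set to zero, used for exact round-trip
#' checks of the inversion pipeline.
#'
#' @param ... Passed to [cohort_config()].
#' @export
noiseless_config <- function(...) {
  cohort_config(q10_noise_sd = 0, q10_protection_effect = 0,
                q10_alkalinity_effect = 0, rate_log_sd = 0,
                co2_noise_sd = 0, delta13c_noise_sd = 0, ...)
}
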