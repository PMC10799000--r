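#' Q10 from the exponential rate constant
#'
#' For the exponential temperature response `R = B * exp(k * T)`, the
#' temperature sensitivity over a 10 degC interval is `Q10 = exp(10 k)`.
#'
#' @param k Rate constant per degC.
#' @return Dimensionless Q10.
#' @export
q10_from_k <- function(k) {
  stopifnot(all(is.finite(k)))
  exp(10 * k)
}

#' Fit an exponential temperature response
#'
#' Fits `R = B * exp(k * T)` to (temperature, rate) points. The default is
#' ordinary least squares on `ln(rate) = ln(B) + k * T`, which is closed-form,
#' deterministic and exact in the noiseless limit; nonlinear least squares on
#' the original scale is available for sensitivity checks. Non-positive or
#' QC-flagged rates are dropped first; the fit is refused when fewer than
#' `min_points` usable points remain.
#'
#' @param temperature,rate Numeric vectors of equal length.
#' @param source Label `"SOC"`, `"SIC"` or `"total"` (determines the QC
#'   R-squared threshold).
#' @param min_points Minimum usable points (default 4 of the 6 nominal
#'   temperatures, preserving residual degrees of freedom).
#' @param method `"log-ols"` (default) or `"nls"`.
#' @return A one-row tibble with `B`, `k`, `q10`, `r_squared`, `n_points`,
#'   `qc_pass`, and `reason` (`NA` when fitted).
#' @export
fit_exponential <- function(temperature, rate, source = "total",
                            min_points = 4, method = c("log-ols", "nls")) {
  method <- match.arg(method)
  stopifnot(length(temperature) == length(rate))
  keep <- is.finite(rate) & is.finite(temperature) & rate > 0
  t_u <- temperature[keep]
  r_u <- rate[keep]
  refuse <- function(reason) {
    tibble::tibble(source = source, B = NA_real_, k = NA_real_,
                   q10 = NA_real_, r_squared = NA_real_,
                   n_points = length(r_u), qc_pass = FALSE, reason = reason)
  }
  if (length(r_u) < min_points) {
    return(refuse(sprintf("only %d positive points (need >= %d)",
                          length(r_u), min_points)))
  }
  if (length(unique(t_u)) < 2) return(refuse("fewer than 2 distinct temperatures"))
  if (method == "log-ols") {
    y <- log(r_u)
    fit <- lm.fit(cbind(1, t_u), y)
    b0 <- fit$coefficients[1]
    k <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_  # flat series
    B <- exp(b0)
  } else {
    start <- list(B = max(mean(r_u), 1e-8), k = 0.07)
    nf <- tryCatch(
      nls(r_u ~ B * exp(k * t_u), start = start,
          control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(nf)) return(refuse("nls failed to converge"))
    B <- coef(nf)[["B"]]
    k <- coef(nf)[["k"]]
    ss_res <- sum(stats::resid(nf)^2)
    ss_tot <- sum((r_u - mean(r_u))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }
  out <- tibble::tibble(source = source, B = unname(B), k = unname(k),
                        q10 = q10_from_k(unname(k)), r_squared = r2,
                        n_points = length(r_u), qc_pass = NA, reason = NA_character_)
  out$qc_pass <- qc_fit(out)
  out
}

#' QC rule for a fitted temperature response
#'
#' A fit passes when its log-linear R-squared exceeds the source-specific
#' threshold: 0.95 for SOC-derived CO2, 0.85 for SIC-derived CO2 (the total
#' flux uses the SOC threshold). Flat series (undefined R-squared) fail.
#'
#' @param fit One or more rows with `source` and `r_squared`.
#' @param r2_soc,r2_sic Thresholds.
#' @return Logical vector.
#' @export
qc_fit <- function(fit, r2_soc = 0.95, r2_sic = 0.85) {
  thr <- ifelse(fit$source == "SIC", r2_sic, r2_soc)
  !is.na(fit$r_squared) & fit$r_squared > thr
}

#' Carbon availability index
#'
#' Ratio of basal respiration to substrate-induced respiration.
#'
#' @param basal,sir Respiration rates (same units).
#' @return Dimensionless CAI.
#' @export
carbon_availability_index <- function(basal, sir) {
  if (any(sir <= 0)) stop("substrate-induced respiration must be > 0")
  basal / sir
}

#' SOC decomposability
#'
#' Fitted basal rate parameter `B` of the SOC-derived response per unit SOC
#' content.
#'
#' @param b_soc Fitted `B` (ug C g^-1 h^-1).
#' @param soc_content SOC content (g C kg^-1).
#' @return D_SOC, (ug C g^-1 h^-1) per (g C kg^-1).
#' @export
soc_decomposability <- function(b_soc, soc_content) {
  if (any(soc_content <= 0)) stop("SOC content must be > 0")
  b_soc / soc_content
}

#' SIC content from carbonate content
#'
#' Multiplies CaCO3 content by 0.12, the mass proportion of C in calcium
#' carbonate.
#'
#' @param caco3 Carbonate content (g kg^-1).
#' @return SIC content (g C kg^-1).
#' @export
sic_from_carbonate <- function(caco3) {
  if (any(caco3 < 0)) stop("carbonate content must be >= 0")
  0.12 * caco3
}

#' Fit temperature responses for every sample and source
#'
#' Runs [fit_exponential()] on the SOC-derived, SIC-derived and total rate
#' series of each sample in a partition table. Records flagged
#' `qc_negative` are excluded before fitting.
#'
#' @param partition Partition table from [partition_all()].
#' @param samples Sample table (to attach depth/moisture labels); optional.
#' @param min_points,method Passed to [fit_exponential()].
#' @param sources Which series to fit per sample.
#' @return One row per sample x source with fit parameters and QC flags.
#' @export
fit_q10_all <- function(partition, samples = NULL, min_points = 4,
                        method = "log-ols",
                        sources = c("SOC", "SIC", "total")) {
  part <- partition
  if ("qc_negative" %in% names(part)) {
    part$rate_total[part$qc_negative] <- NA_real_
    part$r_soc[part$qc_negative] <- NA_real_
    part$r_sic[part$qc_negative] <- NA_real_
  }
  series_col <- c(SOC = "r_soc", SIC = "r_sic", total = "rate_total")
  sp <- split(part, part$sample_id)
  res <- lapply(sp, function(d) {
    dplyr::bind_rows(lapply(sources, function(src) {
      fit_exponential(d$temperature, d[[series_col[[src]]]], src,
                      min_points, method)
    }))
  })
  out <- dplyr::bind_rows(res, .id = "sample_id")
  if (!is.null(samples)) {
    out <- dplyr::left_join(
      out, samples[, c("sample_id", "site_id", "depth", "moisture")],
      by = "sample_id")
    front <- c("sample_id", "site_id", "depth", "moisture")
    out <- out[c(front, setdiff(names(out), front))]
  }
  out
}
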