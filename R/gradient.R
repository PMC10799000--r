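#' Linear regression of a response on the aridity index
#'
#' OLS fit with Pearson correlation, two-sided p value and a 95% confidence
#' interval on the slope. The slope is also reported per 0.1 aridity-index
#' units, the scale on which gradient changes are usually quoted.
#'
#' @param values Response values (e.g. per-site Q10s).
#' @param ai Aridity index, same length.
#' @param label Response label carried into the output.
#' @return One-row tibble: `label`, `slope`, `slope_per_0p1_ai`, `intercept`,
#'   `r`, `p_value`, `ci_lo`, `ci_hi` (95% CI on the slope), `n`.
#' @export
regress_on_aridity <- function(values, ai, label = "response") {
  keep <- is.finite(values) & is.finite(ai)
  values <- values[keep]
  ai <- ai[keep]
  n <- length(values)
  if (n < 3) stop("need at least 3 paired observations")
  if (var(ai) == 0) stop("aridity index has zero variance")
  fit <- lm(values ~ ai)
  slope <- unname(coef(fit)[2])
  # confint warns about "essentially perfect" fits; exact lines are a
  # legitimate input here (noiseless cohorts)
  ci <- suppressWarnings(stats::confint(fit, "ai", level = 0.95))
  if (var(values) == 0) {
    r <- 0
    p <- 1
  } else {
    ct <- cor.test(values, ai)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  tibble::tibble(label = label, slope = slope,
                 slope_per_0p1_ai = slope / 10,
                 intercept = unname(coef(fit)[1]),
                 r = r, p_value = p,
                 ci_lo = ci[1], ci_hi = ci[2], n = n)
}

#' Two-sided paired-sample t test
#'
#' Classical paired t statistic with `df = n - 1`. A zero-variance difference
#' vector is flagged degenerate instead of erroring: identical vectors give
#' `t = 0, p = 1`; a constant non-zero shift gives `t = +/-Inf, p = 0`.
#'
#' @param a,b Paired observations of equal length (`n >= 2`).
#' @return A list with `t`, `df`, `p_value`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_treatment_test <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  degenerate_result <- function() {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    list(t = t_stat, df = n - 1, p_value = if (mean(d) == 0) 1 else 0,
         mean_diff = mean(d), n = n, degenerate = TRUE)
  }
  if (sd(d) == 0) return(degenerate_result())
  # t.test refuses essentially-constant differences; report those as
  # degenerate too rather than erroring
  tt <- tryCatch(t.test(a, b, paired = TRUE), error = function(e) NULL)
  if (is.null(tt)) return(degenerate_result())
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate), n = n,
       degenerate = FALSE)
}

#' Pearson correlation table of Q10s against candidate factors
#'
#' Computes Pearson r and p for each response column against each factor
#' column, aligned by row. Family-wise correction (Holm, applied per response
#' row) is on by default; the conventional significance codes are
#' `*** < 0.001`, `** < 0.01`, `* < 0.05` on the (corrected) p values.
#' Constant factor columns yield an `NA` cell flagged in `note`.
#'
#' @param responses Data frame of response columns (e.g. `q10_soc`,
#'   `q10_sic`).
#' @param factors Data frame of factor columns, same rows.
#' @param correct Apply Holm correction per response row (default TRUE).
#' @return Long tibble: `response`, `factor`, `r`, `p`, `p_adj`, `sig`,
#'   `n`, `note`.
#' @export
correlation_table <- function(responses, factors, correct = TRUE) {
  stopifnot(nrow(responses) == nrow(factors))
  rows <- lapply(names(responses), function(rn) {
    y <- responses[[rn]]
    cells <- lapply(names(factors), function(fn) {
      x <- factors[[fn]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 3 || sd(x[keep]) == 0 || sd(y[keep]) == 0) {
        return(tibble::tibble(response = rn, factor = fn, r = NA_real_,
                              p = NA_real_, n = sum(keep),
                              note = "constant or insufficient data"))
      }
      ct <- cor.test(y[keep], x[keep])
      tibble::tibble(response = rn, factor = fn, r = unname(ct$estimate),
                     p = ct$p.value, n = sum(keep), note = NA_character_)
    })
    row <- dplyr::bind_rows(cells)
    row$p_adj <- if (correct) p.adjust(row$p, method = "holm") else row$p
    row
  })
  out <- dplyr::bind_rows(rows)
  out$sig <- ifelse(is.na(out$p_adj), "",
             ifelse(out$p_adj < 0.001, "***",
             ifelse(out$p_adj < 0.01, "**",
             ifelse(out$p_adj < 0.05, "*", ""))))
  out[c("response", "factor", "r", "p", "p_adj", "sig", "n", "note")]
}

#' Aridity-gradient regressions for a fitted cohort
#'
#' Regresses QC-passed, field-moisture Q10s on the site aridity index,
#' separately per depth and source.
#'
#' @param q10 Fit table from [fit_q10_all()] (with `site_id`, `depth`,
#'   `moisture` attached).
#' @param sites Site table with `site_id`, `aridity_index`.
#' @param sources Sources to analyse.
#' @return One regression row per depth x source.
#' @export
aridity_gradient <- function(q10, sites, sources = c("SOC", "SIC")) {
  dat <- q10[q10$moisture == "field" & q10$qc_pass & q10$source %in% sources, ]
  dat <- dplyr::inner_join(dat, sites[, c("site_id", "aridity_index")],
                           by = "site_id")
  combos <- unique(dat[, c("depth", "source")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    d <- dat[dat$depth == combos$depth[i] & dat$source == combos$source[i], ]
    out <- regress_on_aridity(d$q10, d$aridity_index,
                              sprintf("q10_%s", tolower(combos$source[i])))
    out$depth <- combos$depth[i]
    out$source <- combos$source[i]
    out
  })
  dplyr::bind_rows(res)
}

#' Paired moisture-treatment tests for a fitted cohort
#'
#' For each depth x source, pairs the WHC treatments by site and runs the
#' two-sided paired t test on QC-passed Q10s. Sites missing either member of
#' a pair are dropped pairwise for that comparison only.
#'
#' @param q10 Fit table from [fit_q10_all()].
#' @param pairs List of 2-vectors of moisture levels to compare.
#' @return One row per depth x source x comparison.
#' @export
moisture_tests <- function(q10,
                           pairs = list(c("WHC20", "WHC40"),
                                        c("WHC20", "WHC60"),
                                        c("WHC40", "WHC60"))) {
  dat <- q10[q10$qc_pass & q10$source %in% c("SOC", "SIC"), ]
  combos <- expand.grid(depth = unique(dat$depth),
                        source = c("SOC", "SIC"),
                        pair = seq_along(pairs), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    lv <- pairs[[combos$pair[i]]]
    d <- dat[dat$depth == combos$depth[i] & dat$source == combos$source[i], ]
    a <- d[d$moisture == lv[1], c("site_id", "q10")]
    b <- d[d$moisture == lv[2], c("site_id", "q10")]
    m <- dplyr::inner_join(a, b, by = "site_id", suffix = c("_a", "_b"))
    if (nrow(m) < 2) return(NULL)
    tt <- paired_treatment_test(m$q10_a, m$q10_b)
    tibble::tibble(depth = combos$depth[i], source = combos$source[i],
                   level_a = lv[1], level_b = lv[2], t = tt$t, df = tt$df,
                   p_value = tt$p_value, mean_diff = tt$mean_diff, n = tt$n,
                   degenerate = tt$degenerate)
  })
  dplyr::bind_rows(res)
}

#' Factor correlation table for a fitted cohort
#'
#' Builds the field-moisture, QC-passed Q10_SOC / Q10_SIC rows against the
#' climate, physical, chemical and substrate factor columns for one depth.
#'
#' @param q10 Fit table from [fit_q10_all()].
#' @param samples,sites Generator tables.
#' @param depth Depth layer to analyse.
#' @param correct Holm correction flag, passed on.
#' @return Long correlation table (see [correlation_table()]).
#' @export
q10_correlations <- function(q10, samples, sites, depth = "topsoil",
                             correct = TRUE) {
  fac <- factor_table(q10, samples, sites, depth)
  responses <- fac[, c("q10_soc", "q10_sic")]
  factor_cols <- c("mat", "aridity_index", "oc_ca", "oc_fe", "oc_pom",
                   "oc_maom", "ph", "cec", "ca", "mg", "soc", "sic",
                   "cai", "d_soc")
  correlation_table(responses, fac[, factor_cols], correct = correct)
}

# One row per site for a depth at field moisture: fitted q10s (QC-passed,
# else NA), soil factors, and the derived substrate indices.
factor_table <- function(q10, samples, sites, depth) {
  sam <- samples[samples$depth == depth & samples$moisture == "field", ]
  qd <- q10[q10$depth == depth & q10$moisture == "field", ]
  wide <- tibble::tibble(sample_id = sam$sample_id)
  for (src in c("SOC", "SIC")) {
    qq <- qd[qd$source == src & qd$qc_pass, c("sample_id", "q10")]
    names(qq)[2] <- paste0("q10_", tolower(src))
    wide <- dplyr::left_join(wide, qq, by = "sample_id")
  }
  b_soc <- qd[qd$source == "SOC" & qd$qc_pass, c("sample_id", "B")]
  wide <- dplyr::left_join(wide, b_soc, by = "sample_id")
  out <- dplyr::inner_join(wide, sam, by = "sample_id")
  out <- dplyr::inner_join(out, sites[, c("site_id", "aridity_index", "mat")],
                           by = "site_id")
  out$cai <- carbon_availability_index(out$basal_resp, out$sir_resp)
  out$d_soc <- ifelse(is.na(out$B), NA_real_,
                      soc_decomposability(out$B, out$soc))
  out
}
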