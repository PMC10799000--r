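test_that("q10_from_k matches the closed form and reciprocal symmetry", {
  expect_equal(q10_from_k(0), 1.0)
  expect_equal(q10_from_k(0.0693), 2.000, tolerance = 5e-4)
  expect_equal(q10_from_k(0.1141), 3.13, tolerance = 5e-3)
  k <- seq(-0.2, 0.2, 0.01)
  expect_equal(q10_from_k(-k), 1 / q10_from_k(k))
})

test_that("log-linear fit is exact on noiseless exponential series", {
  temps <- seq(5, 30, 5)
  rates <- 0.05 * exp(0.0693 * temps)
  fit <- fit_exponential(temps, rates, "SOC")
  expect_equal(fit$k, 0.0693, tolerance = 1e-9)
  expect_equal(fit$B, 0.05, tolerance = 1e-9)
  expect_equal(fit$q10, 2.000, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$qc_pass)
  # any two distinct temperatures suffice for exactness
  fit2 <- fit_exponential(c(10, 20, 21, 30), 0.2 * exp(0.11 * c(10, 20, 21, 30)))
  expect_equal(fit2$k, 0.11, tolerance = 1e-9)
  # nls route agrees in the noiseless limit
  fitn <- fit_exponential(temps, rates, "SOC", method = "nls")
  expect_equal(fitn$k, 0.0693, tolerance = 1e-6)
})

test_that("degenerate and filtered series are handled by the point rules", {
  temps <- seq(5, 30, 5)
  flat <- fit_exponential(temps, rep(0.3, 6))
  expect_equal(flat$q10, 1.0)
  expect_false(flat$qc_pass)  # flat series: undefined R2 fails QC
  withneg <- fit_exponential(temps, c(-0.01, 0.1 * exp(0.07 * temps[-1])))
  expect_equal(withneg$n_points, 5)
  expect_equal(withneg$k, 0.07, tolerance = 1e-9)
  few <- fit_exponential(temps, c(0.1, 0.2, 0.3, -1, -1, -1))
  expect_false(few$qc_pass)
  expect_match(few$reason, "positive points")
  zero <- fit_exponential(temps, rep(0, 6))
  expect_false(zero$qc_pass)
})

test_that("QC thresholds are source specific", {
  mk <- function(source, r2) tibble::tibble(source = source, r_squared = r2)
  expect_true(qc_fit(mk("SOC", 0.96)))
  expect_false(qc_fit(mk("SOC", 0.94)))
  expect_true(qc_fit(mk("SIC", 0.86)))
  expect_false(qc_fit(mk("SIC", 0.84)))
  expect_true(all(qc_fit(mk(c("SOC", "SIC", "total"), 1))))
  expect_false(qc_fit(mk("total", 0.94)))  # total uses the SOC threshold
})

test_that("substrate indices are the defining ratios", {
  expect_equal(carbon_availability_index(0.2, 1.0), 0.2)
  expect_equal(carbon_availability_index(0.7, 0.7), 1.0)
  expect_equal(carbon_availability_index(0, 2), 0)
  expect_error(carbon_availability_index(0.2, 0), "> 0")
  expect_equal(soc_decomposability(0.05, 10), 0.005)
  expect_equal(soc_decomposability(0, 10), 0)
  expect_error(soc_decomposability(0.05, 0), "> 0")
  expect_equal(sic_from_carbonate(100), 12.0)
  expect_equal(sic_from_carbonate(0), 0)
  expect_equal(sic_from_carbonate(50), 6.0)
  expect_error(sic_from_carbonate(-1), ">= 0")
})

test_that("k estimator is unbiased under multiplicative log-normal noise", {
  set.seed(99)
  temps <- seq(5, 30, 5)
  true_k <- 0.11
  ks <- replicate(1000, {
    rates <- 0.3 * exp(true_k * temps) * exp(rnorm(6, 0, 0.1))
    fit_exponential(temps, rates)$k
  })
  bias <- mean(ks) - true_k
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(bias), 2 * se)
})

test_that("fitted Q10s recover generator truth within noise on a full cohort", {
  run <- default_run()
  q10 <- run$q10[run$q10$qc_pass & run$q10$source %in% c("SOC", "SIC"), ]
  tr <- merge(q10, run$cohort$truth, by = "sample_id")
  truth <- ifelse(tr$source == "SOC", tr$true_q10_soc, tr$true_q10_sic)
  rmse <- sqrt(mean((tr$q10 - truth)^2))
  # fitting error should stay well below the cohort's Q10 noise scale
  expect_lt(rmse, 2 * 0.25)
})
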