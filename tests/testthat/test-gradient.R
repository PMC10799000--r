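test_that("aridity regression recovers an exact line and degenerate cases", {
  ai <- seq(0.05, 0.6, length.out = 12)
  res <- suppressWarnings(regress_on_aridity(1.65 + 4.7 * ai, ai, "q10_soc"))
  expect_equal(res$slope, 4.7, tolerance = 1e-10)
  expect_equal(res$slope_per_0p1_ai, 0.47, tolerance = 1e-10)
  expect_equal(res$intercept, 1.65, tolerance = 1e-10)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_lt(res$ci_hi - res$ci_lo, 1e-8)  # degenerate-width CI on exact data
  const <- suppressWarnings(regress_on_aridity(rep(2, 12), ai))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$r, 0)
  expect_error(regress_on_aridity(1:5, rep(0.3, 5)), "zero variance")
  expect_error(regress_on_aridity(1:2, c(0.1, 0.2)), "at least 3")
})

test_that("paired t test matches textbook arithmetic and is antisymmetric", {
  same <- paired_treatment_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  tt <- paired_treatment_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(tt$t, -4.0, tolerance = 1e-12)
  expect_equal(tt$df, 2)
  rev <- paired_treatment_test(c(2, 3, 5), c(1, 2, 3))
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p_value, tt$p_value)
  shift <- paired_treatment_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)
})

test_that("correlations are affine invariant and Holm correction is conservative", {
  set.seed(5)
  y <- rnorm(40)
  x <- rnorm(40)
  tab1 <- correlation_table(data.frame(resp = y),
                            data.frame(a = x, b = 3 * x - 7, c = 2 * y + 1),
                            correct = FALSE)
  expect_equal(tab1$r[tab1$factor == "a"], tab1$r[tab1$factor == "b"],
               tolerance = 1e-12)
  expect_equal(tab1$r[tab1$factor == "c"], 1, tolerance = 1e-12)
  tabH <- correlation_table(data.frame(resp = y),
                            data.frame(a = x, b = 3 * x - 7, c = 2 * y + 1))
  expect_true(all(tabH$p_adj >= tabH$p))
  const <- correlation_table(data.frame(resp = y), data.frame(k = rep(1, 40)))
  expect_true(is.na(const$r))
  expect_match(const$note, "constant")
})

test_that("uncorrected correlation test holds its nominal type-I error", {
  set.seed(21)
  hits <- replicate(800, {
    tab <- correlation_table(data.frame(y = rnorm(30)),
                             data.frame(x = rnorm(30)), correct = FALSE)
    tab$p < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("cohort gradient recovers generator slopes within the CI", {
  run <- default_run()
  g <- run$gradient
  expect_equal(nrow(g), 4)  # 2 depths x 2 sources
  soc <- g[g$source == "SOC", ]
  sic <- g[g$source == "SIC", ]
  expect_true(all(soc$slope > 0))
  expect_true(all(sic$slope < 0))
  expect_true(all(soc$ci_lo <= 4.7 & soc$ci_hi >= 4.7))
  expect_true(all(sic$ci_lo <= -3.9 & sic$ci_hi >= -3.9))
  expect_true(all(g$p_value < 0.001))
})

test_that("moisture treatments shift Q10 in opposite directions by source", {
  tt <- default_run()$ttests
  w26 <- tt[tt$level_a == "WHC20" & tt$level_b == "WHC60", ]
  expect_equal(nrow(w26), 4)
  expect_true(all(w26$mean_diff[w26$source == "SOC"] < 0))
  expect_true(all(w26$mean_diff[w26$source == "SIC"] > 0))
  expect_true(all(w26$p_value < 0.01))
})
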