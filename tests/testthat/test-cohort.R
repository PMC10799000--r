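test_that("default cohort has the study's dimensions and aridity span", {
  cohort <- default_run()$cohort
  expect_equal(nrow(cohort$sites), 30)
  expect_equal(nrow(cohort$samples), 240)  # 30 sites x 2 depths x 4 moistures
  expect_true(all(cohort$sites$aridity_index >= 0.04 &
                    cohort$sites$aridity_index <= 0.59))
  expect_true(all(cohort$sites$mat >= -1.2 & cohort$sites$mat <= 10.0))
  # one incubation series of six ascending temperature steps per sample
  steps <- split(cohort$incubation$temperature, cohort$incubation$sample_id)
  expect_true(all(vapply(steps, function(x) identical(x, seq(5, 30, 5)),
                         logical(1))))
  expect_true(all(cohort$incubation$co2_final >= 0))
  expect_true(all(cohort$samples$ph >= 4 & cohort$samples$ph <= 11))
  numeric_cols <- c("soc", "sic", "oc_pom", "oc_maom", "oc_fe", "oc_ca",
                    "cec", "ca", "mg", "basal_resp", "sir_resp")
  expect_true(all(as.matrix(cohort$samples[numeric_cols]) >= 0))
})

test_that("identical seeds give identical cohorts; errors on degenerate config", {
  c1 <- generate_cohort(small_config(seed = 42L))
  c2 <- generate_cohort(small_config(seed = 42L))
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$incubation, c2$incubation)
  c3 <- generate_cohort(small_config(seed = 43L))
  expect_false(identical(c1$incubation, c3$incubation))
  expect_error(cohort_config(n_sites = 2), "n_sites")
  expect_error(cohort_config(moisture_levels = character(0)), "moisture")
})

test_that("source rates follow the exponential forward model and calibration", {
  s <- list(true_b_soc = 0.05, true_k_soc = 0, true_b_sic = 0.05,
            true_k_sic = 0.0693)
  r <- source_rates(s, 30)
  expect_equal(r$r_soc, 0.05)                      # k = 0: flat response
  r10 <- source_rates(s, 10)
  expect_equal(r10$r_sic, 0.1, tolerance = 1e-3)   # e^0.693 = 2
  expect_error(source_rates(list(true_b_soc = 1), 20), "ground-truth")
  # B_sic calibration pins the 20 degC SIC share to the configured value
  cohort <- generate_cohort(small_config())
  tr <- cohort$truth
  r20 <- source_rates(tr, 20)
  f20 <- r20$r_sic / (r20$r_soc + r20$r_sic)
  expect_equal(f20, tr$true_f_sic_20C, tolerance = 1e-12)
  top <- tr$depth == "topsoil"
  expect_equal(unique(tr$true_f_sic_20C[top]), 0.072)
  expect_equal(unique(tr$true_f_sic_20C[!top]), 0.111)
  # c = 0.072 with r_soc(20) = 1 gives r_sic(20) = 0.072/0.928 = 0.0776
  expect_equal(0.072 / (1 - 0.072), 0.0776, tolerance = 1e-3)
})

test_that("generated soil chemistry trends negatively with aridity index", {
  n_reps <- 100
  sig <- matrix(NA, n_reps, 2)
  for (i in seq_len(n_reps)) {
    cfg <- cohort_config(seed = 1000L + i)
    sites <- dryq10:::generate_sites(cfg)
    samples <- dryq10:::generate_samples(cfg, sites)
    field <- samples[samples$moisture == "field", ]
    field <- merge(field, sites[, c("site_id", "aridity_index")],
                   by = "site_id")
    ph_t <- cor.test(field$ph, field$aridity_index)
    sic_t <- cor.test(field$sic, field$aridity_index)
    sig[i, ] <- c(ph_t$estimate < 0 && ph_t$p.value < 0.05,
                  sic_t$estimate < 0 && sic_t$p.value < 0.05)
  }
  expect_gte(mean(sig[, 1]), 0.9)
  expect_gte(mean(sig[, 2]), 0.9)
})

test_that("ground-truth Q10 slopes on aridity match the generating values", {
  slopes <- sapply(1:200, function(i) {
    cfg <- cohort_config(seed = 2000L + i)
    sites <- dryq10:::generate_sites(cfg)
    samples <- dryq10:::generate_samples(cfg, sites)
    field <- samples[samples$moisture == "field", ]
    field <- merge(field, sites[, c("site_id", "aridity_index")],
                   by = "site_id")
    # both depths share the generating slopes; average them
    by_depth <- sapply(split(field, field$depth), function(d) {
      c(coef(lm(true_q10_soc ~ aridity_index, d))[2],
        coef(lm(true_q10_sic ~ aridity_index, d))[2])
    })
    rowMeans(by_depth)
  })
  expect_lt(abs(mean(slopes[1, ]) - 4.7), 0.05)
  expect_lt(abs(mean(slopes[2, ]) - (-3.9)), 0.05)
})

test_that("single-sample synthesis matches the protocol and zero-rate limit", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  sample <- merge(cohort$samples[1, ], cohort$truth[1, ])
  set.seed(1)
  steps <- synthesize_incubation(sample, cfg)
  expect_equal(steps$temperature, seq(5, 30, 5))
  expect_true(all(steps$co2_initial == 0))
  zero <- sample
  zero$true_b_soc <- zero$true_b_sic <- 0
  cfg0 <- noiseless_config(n_sites = 10)
  steps0 <- synthesize_incubation(zero, cfg0)
  expect_true(all(steps0$co2_final == 0))  # flushed jar stays at 0 ppm
})
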