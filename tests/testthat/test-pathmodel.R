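test_that("composite scores follow the correlation-matrix PC1 conventions", {
  set.seed(11)
  x <- rnorm(50)
  perfect <- data.frame(a = x, b = 2 * x + 3)
  cp <- composite_scores(perfect, c("a", "b"))
  expect_equal(cp$variance_explained, 1.0, tolerance = 1e-12)
  expect_gt(cp$loadings[["a"]], 0)
  # exactly uncorrelated pair: eigenvalues of the 2x2 identity
  y <- rnorm(50)
  y_orth <- residuals(lm(y ~ x))
  cp2 <- composite_scores(data.frame(a = x, b = y_orth), c("a", "b"))
  expect_equal(cp2$variance_explained, 0.5, tolerance = 1e-12)
  # reflection: negating one member flips its loading, scores stay equivalent
  z <- rnorm(50)
  d <- data.frame(a = x + rnorm(50, 0, 0.3), b = x + z, c = x - z)
  c1 <- composite_scores(d, c("a", "b", "c"))
  d2 <- d
  d2$b <- -d2$b
  c2 <- composite_scores(d2, c("a", "b", "c"))
  expect_equal(c2$loadings[["b"]], -c1$loadings[["b"]], tolerance = 1e-12)
  expect_equal(abs(cor(c1$scores, c2$scores)), 1, tolerance = 1e-12)
  d$k <- 1
  expect_error(composite_scores(d, c("a", "k")), "k")
})

test_that("single-edge and saturated models reduce to closed forms", {
  set.seed(12)
  x <- rnorm(200)
  y <- 0.5 * x + rnorm(200)
  m <- fit_path_model(data.frame(x = x, y = y),
                      data.frame(from = "x", to = "y"))
  expect_equal(m$dag$coefficient, cor(x, y), tolerance = 1e-12)
  # saturated recursive model reproduces the sample covariance exactly
  z <- 0.3 * x - 0.4 * y + rnorm(200)
  dag <- data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"))
  ms <- fit_path_model(data.frame(x = x, y = y, z = z), dag)
  expect_equal(unname(dryq10:::implied_covariance(ms)), unname(ms$S),
               tolerance = 1e-10)
  expect_equal(ms$fit$df, 0)
  expect_equal(ms$fit$chi2, 0, tolerance = 1e-8)
  expect_equal(ms$fit$rmsea, 0)
  expect_equal(ms$fit$gfi, 1, tolerance = 1e-8)
  cyc <- data.frame(from = c("x", "y"), to = c("y", "x"))
  expect_error(fit_path_model(data.frame(x = x, y = y), cyc), "cycle")
})

test_that("standardized coefficients are invariant to affine rescaling", {
  set.seed(13)
  x <- rnorm(150)
  m <- 0.6 * x + rnorm(150, 0, 0.8)
  y <- 0.5 * m - 0.2 * x + rnorm(150, 0, 0.7)
  dag <- data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"))
  f1 <- fit_path_model(data.frame(x = x, m = m, y = y), dag)
  f2 <- fit_path_model(data.frame(x = 100 * x - 3, m = m / 7, y = 2 * y), dag)
  expect_equal(f1$dag$coefficient, f2$dag$coefficient, tolerance = 1e-10)
})

test_that("chain simulation recovers generating coefficients", {
  set.seed(14)
  n <- 1e4
  x <- rnorm(n)
  m <- 0.6 * x + sqrt(1 - 0.6^2) * rnorm(n)
  y <- 0.5 * m + sqrt(1 - 0.5^2) * rnorm(n)
  dag <- data.frame(from = c("x", "m"), to = c("m", "y"))
  fit <- fit_path_model(data.frame(x = x, m = m, y = y), dag)
  expect_equal(fit$dag$coefficient[1], 0.6, tolerance = 0.03)
  expect_equal(fit$dag$coefficient[2], 0.5, tolerance = 0.03)
  ef <- effect_decomposition(fit, "y")
  expect_equal(ef$total[ef$predictor == "x"], 0.6 * 0.5, tolerance = 0.05)
})

test_that("effect decomposition matches hand path-tracing on a chain", {
  dag <- data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"),
                    coefficient = c(0.6, 0.5, -0.2))
  ef <- effect_decomposition(manual_path_model(dag, "y"), "y")
  x_row <- ef[ef$predictor == "x", ]
  expect_equal(x_row$direct, -0.2)
  expect_equal(x_row$indirect, 0.30)
  expect_equal(x_row$total, 0.10, tolerance = 1e-12)
  # node with no outgoing paths to the response has all-zero effects
  dag2 <- data.frame(from = c("x", "z"), to = c("y", "w"),
                     coefficient = c(0.4, 0.9))
  ef2 <- effect_decomposition(manual_path_model(dag2, "y"), "y")
  z_row <- ef2[ef2$predictor == "z", ]
  expect_equal(z_row$total, 0)
})

test_that("matrix-power effects equal brute-force enumeration on all small DAGs", {
  set.seed(15)
  checked <- 0
  for (dag in all_dags(3)) {
    dag$coefficient <- runif(nrow(dag), -1, 1)
    nodes <- unique(c(dag$from, dag$to))
    for (resp in nodes) {
      ef <- effect_decomposition(manual_path_model(dag, resp), resp)
      oracle <- enumerate_total_effects(dag, resp)
      expect_equal(ef$total[match(names(oracle), ef$predictor)],
                   unname(oracle), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
  for (i in 1:200) {
    dag <- random_dag(sample(4:6, 1))
    if (is.null(dag)) next
    dag$coefficient <- runif(nrow(dag), -1, 1)
    nodes <- unique(c(dag$from, dag$to))
    resp <- sample(nodes, 1)
    ef <- effect_decomposition(manual_path_model(dag, resp), resp)
    oracle <- enumerate_total_effects(dag, resp)
    expect_equal(ef$total[match(names(oracle), ef$predictor)],
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("chi-square statistic has the reference distribution under truth", {
  # data generated from the default diagram structure; misfit df = 3
  set.seed(16)
  gen <- function(n) {
    cl <- rnorm(n)
    ph <- 0.5 * cl + sqrt(0.75) * rnorm(n)
    ch <- -0.4 * cl + sqrt(0.84) * rnorm(n)
    su <- 0.3 * cl + sqrt(0.91) * rnorm(n)
    q10 <- 0.3 * cl - 0.3 * ph + 0.2 * ch + 0.2 * su + 0.6 * rnorm(n)
    data.frame(climate = cl, physical = ph, chemical = ch, substrate = su,
               q10 = q10)
  }
  dag <- default_dag("q10")
  chis <- replicate(400, {
    m <- fit_path_model(gen(200), dag)
    m$fit$chi2
  })
  m1 <- fit_path_model(gen(500), dag)
  expect_equal(m1$fit$df, 3)
  expect_lt(abs(mean(chis) - 3) / 3, 0.10)  # chi2 mean equals its df
})

test_that("cohort path models give the expected total-effect directions", {
  run <- default_run()
  eff_soc <- run$paths$q10_soc$effects
  eff_sic <- run$paths$q10_sic$effects
  expect_lt(eff_soc$total[eff_soc$predictor == "physical"], 0)
  expect_gt(eff_sic$total[eff_sic$predictor == "chemical"], 0)
  expect_equal(eff_soc$direct + eff_soc$indirect, eff_soc$total,
               tolerance = 1e-12)
  ve <- vapply(run$paths$q10_soc$composites,
               function(cp) cp$variance_explained, numeric(1))
  expect_true(all(ve > 0 & ve <= 1))
})
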