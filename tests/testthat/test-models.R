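test_that("a noiseless generative model is recovered exactly", {
  cfg <- cohort_config(seed = 5)
  cfg$outcome_models <- lapply(cfg$outcome_models, function(om) {
    om$resid_sd <- 0
    om
  })
  coh <- generate_cohort(cfg)
  fit <- fit_ancova(coh, "gwg_kg", "pei_upf", maternal_covariates(),
                    forced = c("pei_upf:weight_status", "pei_upf:age"))
  td <- tidy(fit)
  truth <- c(pei_upf = 1.33, age = 2.6, moderate_pa_pct = -0.2,
             energy_kcal_per_day = 0.003, fat_g_per_day = -0.06,
             "raceAfricanAmerican_other" = -7.9, "clinichigh_income" = -2.0,
             "weight_statusobese" = -5.1, "pei_upf:age" = -0.05,
             "pei_upf:weight_statusobese" = 0.06)
  for (term in names(truth)) {
    expect_equal(td$estimate[td$term == term], unname(truth[term]),
                 tolerance = 1e-8)
  }
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("the OLS path equals brute-force normal equations", {
  set.seed(31)
  n <- 30
  d <- tibble::tibble(
    y = rnorm(n), x = rnorm(n), u = rnorm(n), v = rnorm(n),
    g = factor(sample(c("a", "b"), n, TRUE))
  )
  fit <- fit_ancova(d, "y", "x", c("u", "v", "g"), forced = "x:u")
  X <- cbind(1, d$x, d$u, d$v, as.numeric(d$g == "b"), d$x * d$u)
  beta <- ols_brute(X, d$y)
  expect_equal(unname(tidy(fit)$estimate), unname(beta), tolerance = 1e-8)

  # confidence bounds bracket the estimate; adjusted never exceeds raw R^2
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_lte(glance(fit)$adj.r.squared, glance(fit)$r.squared)
})

test_that("rank-deficient designs and missing data are rejected", {
  set.seed(8)
  d <- tibble::tibble(y = rnorm(20), x = rnorm(20))
  d$x2 <- d$x
  expect_error(fit_ancova(d, "y", "x", "x2"), "collinear")
  # candidate identical to an existing base term
  expect_error(screen_interactions(d, "y", "x", character(),
                                   candidates = "x2"),
               "collinear")
  d$x[3] <- NA
  expect_error(fit_ancova(d, "y", "x", character()), "missing values")
})

test_that("screening retains a strong interaction and is order independent", {
  set.seed(12)
  n <- 50
  d <- tibble::tibble(x = rnorm(n), u = rnorm(n), w = rnorm(n))
  d$y <- 1 + 2 * d$x + 0.5 * d$u + 3 * d$x * d$u # noiseless interaction
  sc <- screen_interactions(d, "y", "x", c("u", "w"),
                            candidates = c("x:u", "x:w"))
  expect_true(sc$retained[sc$term == "x:u"])
  sc_rev <- screen_interactions(d, "y", "x", c("u", "w"),
                                candidates = c("x:w", "x:u"))
  expect_equal(dplyr::arrange(sc, term), dplyr::arrange(sc_rev, term))

  fit <- suppressWarnings( # noiseless fixture: "essentially perfect fit"
    fit_ancova(d, "y", "x", c("u", "w"), candidates = c("x:u", "x:w")))
  expect_true("x:u" %in% fit$design$retained)
})

test_that("adding a pure-noise regressor lowers adjusted R^2 on average", {
  set.seed(77)
  delta_adj <- delta_raw <- numeric(60)
  for (i in 1:60) {
    n <- 40
    d <- tibble::tibble(x = rnorm(n), z = rnorm(n))
    d$y <- 1 + d$x + rnorm(n)
    f0 <- fit_ancova(d, "y", "x", character())
    f1 <- fit_ancova(d, "y", "x", "z")
    delta_raw[i] <- f1$r_squared - f0$r_squared
    delta_adj[i] <- f1$adj_r_squared - f0$adj_r_squared
  }
  expect_true(all(delta_raw >= -1e-12))
  expect_lt(mean(delta_adj), 0)
})

test_that("pearson_ci handles exact correlation and rejects degenerate input", {
  x <- c(1, 2, 4, 7, 9)
  res <- pearson_ci(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_error(pearson_ci(x, rep(1, 5)), "zero variance")
  expect_error(pearson_ci(x[1:3], x[1:3]), "at least 4")
  expect_error(pearson_ci(c(x[-5], NA), x), "finite")
})

test_that("Fisher-z intervals cover a true correlation near nominal rate", {
  rho <- -0.7
  n <- 45
  B <- 500
  covered <- logical(B)
  set.seed(2024)
  for (i in 1:B) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_ci(z1, z2)
    covered[i] <- ci$conf.low <= rho && rho <= ci$conf.high
  }
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("diagnostics flag a heteroscedastic fit and stay quiet when perfect", {
  set.seed(99)
  n <- 200
  d <- tibble::tibble(x = runif(n, 1, 5))
  mu <- 2 + 3 * d$x
  d$y <- mu + rnorm(n, 0, sqrt(0.6 * mu))
  rej <- 0
  for (i in 1:30) {
    d$y <- mu + rnorm(n, 0, sqrt(0.6 * mu))
    dg <- diagnose_fit(fit_ancova(d, "y", "x", character()))
    rej <- rej + dg$flag[dg$test == "heteroscedasticity_sq_resid"]
  }
  expect_gt(rej / 30, 0.5)

  # a numerically perfect fit has nothing to test: no flags, not computable
  lin <- tibble::tibble(x = 1:20, y = 2 + 3 * (1:20))
  dg <- suppressWarnings(diagnose_fit(fit_ancova(lin, "y", "x", character())))
  expect_true(all(!dg$computable))
  expect_true(all(!dg$flag))
  expect_equal(nrow(dg), 4L)
})
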