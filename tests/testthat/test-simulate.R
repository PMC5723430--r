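test_that("the cohort generator is deterministic and exactly stratified", {
  cfg <- cohort_config(seed = 13)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 45L)
  expect_equal(sum(c1$weight_status == "lean"), 16L)
  expect_equal(sum(c1$weight_status == "obese"), 29L)
  expect_true(all(c1$pei_upf >= 0 & c1$pei_upf <= 100))
  expect_true(all(c1$hei2010 >= 0 & c1$hei2010 <= 100))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(hei_corr = -1), "hei_corr")
  expect_error(cohort_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(pei_upf_sd = 0), "pei_upf_sd")
})

test_that("with zero residual SD the outcomes equal the linear predictor", {
  cfg <- cohort_config(seed = 5)
  cfg$outcome_models <- lapply(cfg$outcome_models, function(om) {
    om$resid_sd <- 0
    om
  })
  coh <- generate_cohort(cfg)
  # an OLS fit of the correct design must then be an exact interpolation
  fit <- fit_ancova(coh, "neonate_bodyfat_pct", "pei_upf",
                    neonatal_covariates(),
                    forced = c("pei_upf:weight_status", "pei_upf:age"))
  expect_lt(max(abs(residuals(fit$model))), 1e-8)
})

test_that("large cohorts reproduce the configured moments and correlation", {
  cfg <- cohort_config(n_subjects = 1000, seed = 314)
  coh <- generate_cohort(cfg)
  se_mean <- 13.2 / sqrt(1000)
  expect_lt(abs(mean(coh$pei_upf) - 54.4), 3 * se_mean)
  expect_lt(abs(sd(coh$pei_upf) - 13.2), 1.5)
  r <- cor(coh$pei_upf, coh$hei2010)
  se_r <- (1 - 0.74^2) / sqrt(1000)
  expect_lt(abs(r - (-0.74)), 3 * se_r + 0.01)
  expect_lt(abs(mean(coh$hei2010) - 62.2), 3 * 13.0 / sqrt(1000))
  expect_lt(abs(mean(coh$age) - 27.2), 3 * 5.1 / sqrt(1000))
  # intercept solving keeps the outcome means on target
  expect_lt(abs(mean(coh$gwg_kg) - 12.0), 1.5)
})

test_that("truncated-normal moment matching corrects truncation bias", {
  # a margin truncated hard at zero: the naive parameters would be biased
  par <- upfdiet:::truncnorm_match(10, 8, 0, 100)
  mm <- upfdiet:::truncnorm_moments(par["mu"], par["sigma"], 0, 100)
  expect_equal(unname(mm["mean"]), 10, tolerance = 1e-6)
  expect_equal(unname(mm["sd"]), 8, tolerance = 1e-6)
})

test_that("generated responses realise their assigned UPF shares", {
  inst <- default_instrument()
  foods <- default_food_table()
  cfg <- cohort_config(n_subjects = 20, seed = 8, missing_rate = 0)
  gen <- generate_responses(cfg, inst, foods)
  expect_false(anyNA(gen$responses$freq_opt[
    foods$kind[match(gen$responses$item_id, foods$item_id)] != "condiment"]))
  # closed loop through the scoring engine: achieved == scored exactly
  prof <- score_intake(gen$responses_complete, foods, inst)
  scored <- prof$subjects$pei_upf[match(gen$targets$subject_id,
                                        prof$subjects$subject_id)]
  expect_equal(scored, gen$targets$achieved, tolerance = 1e-9)
  expect_lt(abs(mean(gen$targets$achieved) - mean(gen$targets$target)), 2)
  expect_lt(mean(abs(gen$targets$achieved - gen$targets$target)), 1)
})

test_that("a single ultra-processed item can carry a 100% target", {
  inst <- tiny_instrument()
  foods <- fruit_soda_foods()
  cfg <- cohort_config(n_subjects = 3, seed = 2, missing_rate = 0,
                       pei_upf_mean = 99, pei_upf_sd = 0.1)
  gen <- generate_responses(cfg, inst, foods)
  prof <- score_intake(gen$responses_complete, foods, inst)
  expect_true(all(prof$subjects$pei_upf > 95))
})

test_that("masking respects the configured missingness rate", {
  inst <- default_instrument()
  foods <- default_food_table()
  gen0 <- generate_responses(cohort_config(n_subjects = 10, seed = 3,
                                           missing_rate = 0), inst, foods)
  expect_identical(gen0$responses, gen0$responses_complete)
  gen <- generate_responses(cohort_config(n_subjects = 30, seed = 3,
                                          missing_rate = 0.1), inst, foods)
  kind <- foods$kind[match(gen$responses$item_id, foods$item_id)]
  n_applicable <- sum(kind != "condiment") + sum(kind == "condiment") +
    nrow(gen$responses)
  n_masked <- sum(is.na(gen$responses$freq_opt) & kind != "condiment") +
    sum(is.na(gen$responses$cond_frac_opt) & kind == "condiment") +
    sum(is.na(gen$responses$amount_opt))
  rate <- n_masked / n_applicable
  expect_gt(rate, 0.06)
  expect_lt(rate, 0.14)
})
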