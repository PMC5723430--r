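test_that("energy recomputation matches the macronutrient formula exactly", {
  expect_identical(recompute_energy(0, 0, 0), 0)
  expect_equal(recompute_energy(100, 0, 0), 1.7, tolerance = 1e-15)
  expect_equal(recompute_energy(0, 0, 100), 3.7, tolerance = 1e-15)
  # hand evaluation: 0.017 * (10 + 5) + 0.037 * 4 = 0.403
  expect_equal(recompute_energy(10, 5, 4), 0.403, tolerance = 1e-15)
  expect_error(recompute_energy(-1, 0, 0), "non-negative")
})

test_that("energy recomputation is additive and positively homogeneous", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(3, 0, 50)
    b <- runif(3, 0, 50)
    k <- runif(1, 0, 5)
    expect_equal(recompute_energy(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
                 recompute_energy(a[1], a[2], a[3]) +
                   recompute_energy(b[1], b[2], b[3]))
    expect_equal(recompute_energy(k * a[1], k * a[2], k * a[3]),
                 k * recompute_energy(a[1], a[2], a[3]))
  }
})

test_that("grams/day follows frequency x portion / days-per-month", {
  inst <- tiny_instrument()
  foods <- make_food_table(
    dplyr::bind_rows(
      comp_row("staple", serv = c(50, 100, 200)),
      comp_row("sauce", kind = "condiment", attached_to = "staple",
               serv = c(5, 10, 20))
    ),
    dplyr::bind_rows(nova_row("staple", 1L, "grains"),
                     nova_row("sauce", 4L, "sauces_and_dressings"))
  )
  resp <- tibble::tibble(
    subject_id = "S1",
    item_id = c("staple", "sauce"),
    freq_opt = c(7L, NA),          # 1/day = 30.4 times per month
    amount_opt = c(2L, 2L),        # medium: 100 g and 10 g
    cond_frac_opt = c(NA, 3L)      # half of the time
  )
  g <- grams_per_day(resp, foods, inst)
  # 30.4 * 100 / 30.4 and 0.5 * 30.4 * 10 / 30.4
  expect_equal(g$grams_per_day[g$item_id == "staple"], 100)
  expect_equal(g$grams_per_day[g$item_id == "sauce"], 5)

  never <- resp
  never$freq_opt[1] <- 1L
  g0 <- grams_per_day(never, foods, inst)
  expect_equal(g0$grams_per_day, c(0, 0)) # condiment rides on "never" too

  incomplete <- resp
  incomplete$freq_opt[1] <- NA
  expect_error(grams_per_day(incomplete, foods, inst), "incomplete response")
})

test_that("single-group and symmetric intakes give the expected UPF shares", {
  inst <- tiny_instrument()
  foods <- fruit_soda_foods()
  only_soda <- tibble::tibble(subject_id = "S1", item_id = c("apple", "soda"),
                              freq_opt = c(1L, 4L), amount_opt = c(1L, 2L),
                              cond_frac_opt = NA_integer_)
  prof <- score_intake(only_soda, foods, inst)
  expect_equal(prof$subjects$pei_upf, 100)

  # two items engineered to identical recomputed energy intake
  foods2 <- make_food_table(
    dplyr::bind_rows(
      comp_row("a", serv = c(100, 100, 100), carb = 10, protein = 10, fat = 0),
      comp_row("b", serv = c(100, 100, 100), carb = 10, protein = 10, fat = 0)
    ),
    dplyr::bind_rows(nova_row("a", 1L, "fruits"),
                     nova_row("b", 4L, "candy_and_chocolate"))
  )
  half <- tibble::tibble(subject_id = "S1", item_id = c("a", "b"),
                         freq_opt = c(7L, 7L), amount_opt = c(2L, 2L),
                         cond_frac_opt = NA_integer_)
  expect_equal(score_intake(half, foods2, inst)$subjects$pei_upf, 50)
})

test_that("scoring agrees with an independent item-by-item accumulation", {
  inst <- tiny_instrument()
  foods <- default_food_table()[1:10, ] |> validate_food_table()
  resp <- random_responses(foods, inst, n_subjects = 5, seed = 99)
  prof <- score_intake(resp, foods, inst)
  oracle <- brute_pei(resp, foods, inst)
  merged <- dplyr::inner_join(prof$subjects, oracle, by = "subject_id",
                              suffix = c("", "_oracle"))
  expect_equal(merged$energy_MJ, merged$energy_MJ_oracle, tolerance = 1e-12)
  expect_equal(merged$pei_upf, merged$pei_upf_oracle, tolerance = 1e-12)
})

test_that("a worked three-item profile matches its hand computation", {
  inst <- tiny_instrument()
  foods <- make_food_table(
    dplyr::bind_rows(
      comp_row("porridge", serv = c(100, 200, 300), carb = 12, protein = 3,
               fat = 2, sugars = 1, fiber = 2, sodium = 5),
      comp_row("cookie", serv = c(30, 60, 90), carb = 60, protein = 5,
               fat = 20, sugars = 30, fiber = 1, sodium = 300),
      comp_row("cola", kind = "beverage", serv = c(240, 360, 600), carb = 11,
               protein = 0, fat = 0, sugars = 11, fiber = 0, sodium = 4)
    ),
    dplyr::bind_rows(nova_row("porridge", 1L, "grains"),
                     nova_row("cookie", 4L, "cakes_cookies_and_pies"),
                     nova_row("cola", 4L, "soft_drinks"))
  )
  resp <- tibble::tibble(
    subject_id = "S1", item_id = c("porridge", "cookie", "cola"),
    freq_opt = c(7L, 5L, 4L), amount_opt = c(2L, 1L, 2L),
    cond_frac_opt = NA_integer_
  )
  # spreadsheet-style hand computation:
  # porridge: 30.4 * 200 / 30.4 = 200 g/d -> E = .017*(24+6)+.037*4  = 0.658 MJ
  # cookie:   15.2 * 30 / 30.4  =  15 g/d -> E = .017*(9+.75)+.037*3 = 0.27675
  # cola:     30.4 * 360 / 30.4 = 360 g/d -> E = .017*39.6           = 0.6732
  prof <- score_intake(resp, foods, inst)
  expect_equal(prof$subjects$energy_MJ, 0.658 + 0.27675 + 0.6732,
               tolerance = 1e-12)
  expect_equal(prof$subjects$pei_upf,
               100 * (0.27675 + 0.6732) / (0.658 + 0.27675 + 0.6732),
               tolerance = 1e-12)
})

test_that("group and subgroup accumulations conserve subject totals", {
  inst <- default_instrument()
  foods <- default_food_table()
  resp <- random_responses(foods, inst, n_subjects = 40, seed = 3)
  prof <- score_intake(resp, foods, inst)
  nutrients <- c("energy_MJ", "carb_g", "protein_g", "fat_g", "sugars_g",
                 "fiber_g", "sodium_mg")

  by_group_tot <- prof$by_group |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrients), sum))
  merged <- dplyr::inner_join(by_group_tot, prof$subjects, by = "subject_id",
                              suffix = c("_grp", ""))
  for (nu in nutrients) {
    expect_equal(merged[[paste0(nu, "_grp")]], merged[[nu]], tolerance = 1e-9)
  }

  sub_tot <- prof$by_subgroup |>
    dplyr::group_by(subject_id, nova_group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrients), sum),
                     .groups = "drop")
  merged2 <- dplyr::inner_join(sub_tot, prof$by_group,
                               by = c("subject_id", "nova_group"),
                               suffix = c("_sub", ""))
  for (nu in nutrients) {
    expect_equal(merged2[[paste0(nu, "_sub")]], merged2[[nu]],
                 tolerance = 1e-9)
  }

  pei_tot <- prof$pei |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(total = sum(percent_energy))
  expect_equal(pei_tot$total, rep(100, nrow(pei_tot)), tolerance = 1e-9)
  expect_true(all(prof$pei$percent_energy >= 0 &
                    prof$pei$percent_energy <= 100))
})

test_that("doubling frequency midpoints doubles intakes but not shares", {
  inst <- tiny_instrument()
  doubled <- inst
  doubled$food_frequency$times_per_month <-
    2 * inst$food_frequency$times_per_month
  doubled$beverage_frequency$times_per_month <-
    2 * inst$beverage_frequency$times_per_month
  foods <- fruit_soda_foods()
  resp <- tibble::tibble(subject_id = "S1", item_id = c("apple", "soda"),
                         freq_opt = c(5L, 3L), amount_opt = c(2L, 2L),
                         cond_frac_opt = NA_integer_)
  p1 <- score_intake(resp, foods, inst)
  p2 <- score_intake(resp, foods, doubled)
  expect_equal(p2$subjects$energy_MJ, 2 * p1$subjects$energy_MJ)
  expect_equal(p2$per_item$grams_per_day, 2 * p1$per_item$grams_per_day)
  expect_equal(p2$subjects$pei_upf, p1$subjects$pei_upf)
})

test_that("zero total intake is an explicit error naming the subject", {
  inst <- tiny_instrument()
  foods <- fruit_soda_foods()
  resp <- tibble::tibble(subject_id = "S9", item_id = c("apple", "soda"),
                         freq_opt = c(1L, 1L), amount_opt = c(2L, 2L),
                         cond_frac_opt = NA_integer_)
  expect_error(score_intake(resp, foods, inst), "zero total energy.*S9")
})

test_that("group share table decomposes cohort intake with a 100% total row", {
  inst <- tiny_instrument()
  foods <- fruit_soda_foods()
  one <- tibble::tibble(subject_id = "S1", item_id = c("apple", "soda"),
                        freq_opt = c(6L, 1L), amount_opt = c(2L, 2L),
                        cond_frac_opt = NA_integer_)
  shares <- group_share_table(score_intake(one, foods, inst))
  g1 <- shares[shares$food_group == "1", ]
  expect_equal(g1$energy_pct, 100)
  expect_equal(g1$carb_pct, 100)
  expect_equal(g1$fiber_pct, 100)

  # mirrored pair: S1 eats only fruit, S2 drinks only soda, equal energy
  foods2 <- make_food_table(
    dplyr::bind_rows(
      comp_row("a", serv = c(100, 100, 100), carb = 20, protein = 5, fat = 2,
               sugars = 10, fiber = 1, sodium = 10),
      comp_row("b", serv = c(100, 100, 100), carb = 20, protein = 5, fat = 2,
               sugars = 10, fiber = 1, sodium = 10)
    ),
    dplyr::bind_rows(nova_row("a", 1L, "fruits"),
                     nova_row("b", 4L, "soft_drinks"))
  )
  pair <- tibble::tibble(
    subject_id = c("S1", "S1", "S2", "S2"),
    item_id = c("a", "b", "a", "b"),
    freq_opt = c(7L, 1L, 1L, 7L),
    amount_opt = 2L, cond_frac_opt = NA_integer_
  )
  prof <- score_intake(pair, foods2, inst)
  for (method in c("cohort_sum", "subject_mean")) {
    sh <- group_share_table(prof, method = method)
    expect_equal(sh$energy_pct[sh$food_group == "1"], 50)
    expect_equal(sh$energy_pct[sh$food_group == "4"], 50)
  }
  sh <- group_share_table(prof)
  total <- sh[sh$food_group == "TOTAL", ]
  for (col in grep("_pct$", names(sh), value = TRUE)) {
    expect_equal(total[[col]], 100, tolerance = 0.1)
  }
})
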