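# in-code fixtures and independent oracles shared across test files

tiny_instrument <- function(days_per_month = 30.4) {
  ffq_instrument(
    food_frequency = tibble::tibble(
      label = c("never", "1/mo or less", "2-3/mo", "1-2/wk", "3-4/wk",
                "5-6/wk", "1/day", "2+/day"),
      times_per_month = c(0, 0.5, 2.5, 6.514285714285714, 15.2,
                          23.885714285714286, 30.4, 60.8)
    ),
    beverage_frequency = tibble::tibble(
      label = c("never", "1/mo or less", "1-2/wk", "1/day", "2-3/day",
                "6+/day"),
      times_per_month = c(0, 0.5, 6.514285714285714, 30.4, 76, 182.4)
    ),
    condiment_fraction = tibble::tibble(
      label = c("never", "1/4", "1/2", "3/4", "always"),
      fraction = c(0, 0.25, 0.5, 0.75, 1)
    ),
    days_per_month = days_per_month
  )
}

comp_row <- function(item_id, kind = "food", attached_to = NA_character_,
                     serv = c(50, 100, 200), carb = 10, protein = 2,
                     fat = 1, sugars = 5, fiber = 1, sodium = 10) {
  tibble::tibble(
    item_id = item_id, name = item_id, kind = kind,
    attached_to = attached_to,
    serv_small_g = serv[1], serv_med_g = serv[2], serv_large_g = serv[3],
    carb_g = carb, protein_g = protein, fat_g = fat, sugars_g = sugars,
    fiber_g = fiber, sodium_mg = sodium
  )
}

nova_row <- function(item_id, group, subgroup) {
  tibble::tibble(item_id = item_id, nova_group = group,
                 nova_subgroup = subgroup, note = NA_character_)
}

make_food_table <- function(comp, nova) {
  cp <- tempfile(fileext = ".csv")
  np <- tempfile(fileext = ".csv")
  readr::write_csv(comp, cp, na = "")
  readr::write_csv(nova, np, na = "")
  read_food_table(cp, np)
}

# a two-item food list: a group-1 fruit and a group-4 soda (beverage)
fruit_soda_foods <- function() {
  make_food_table(
    dplyr::bind_rows(
      comp_row("apple", carb = 14, protein = 0.3, fat = 0.2, sugars = 10,
               fiber = 2.4, sodium = 1),
      comp_row("soda", kind = "beverage", serv = c(240, 360, 600),
               carb = 11, protein = 0, fat = 0, sugars = 11, fiber = 0,
               sodium = 4)
    ),
    dplyr::bind_rows(
      nova_row("apple", 1L, "fruits"),
      nova_row("soda", 4L, "soft_drinks")
    )
  )
}

# independent brute-force OLS via the normal equations
ols_brute <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# independent item-by-item accumulation oracle for the scoring path:
# plain loops, no matrix ops, no shared code with score_intake()
brute_pei <- function(responses, foods, inst) {
  out <- list()
  for (sid in unique(responses$subject_id)) {
    rs <- responses[responses$subject_id == sid, ]
    e_by_group <- c(0, 0, 0, 0)
    for (i in seq_len(nrow(rs))) {
      item <- foods[foods$item_id == rs$item_id[i], ]
      if (item$kind == "condiment") {
        main <- rs[rs$item_id == item$attached_to, ]
        main_item <- foods[foods$item_id == item$attached_to, ]
        main_tpm <- if (main_item$kind == "beverage") {
          inst$beverage_frequency$times_per_month[main$freq_opt]
        } else {
          inst$food_frequency$times_per_month[main$freq_opt]
        }
        tpm <- inst$condiment_fraction$fraction[rs$cond_frac_opt[i]] * main_tpm
      } else if (item$kind == "beverage") {
        tpm <- inst$beverage_frequency$times_per_month[rs$freq_opt[i]]
      } else {
        tpm <- inst$food_frequency$times_per_month[rs$freq_opt[i]]
      }
      serv <- c(item$serv_small_g, item$serv_med_g,
                item$serv_large_g)[rs$amount_opt[i]]
      g <- tpm * serv / inst$days_per_month
      e <- 0.017 * (g * item$carb_g / 100 + g * item$protein_g / 100) +
        0.037 * g * item$fat_g / 100
      e_by_group[item$nova_group] <- e_by_group[item$nova_group] + e
    }
    out[[sid]] <- tibble::tibble(
      subject_id = sid,
      energy_MJ = sum(e_by_group),
      pei_upf = 100 * e_by_group[4] / sum(e_by_group)
    )
  }
  dplyr::bind_rows(out)
}

# uniformly random complete responses for the packaged food list
random_responses <- function(foods, inst, n_subjects, seed) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("R%04d", s)
    is_cond <- foods$kind == "condiment"
    n_freq <- ifelse(foods$kind == "beverage",
                     nrow(inst$beverage_frequency),
                     nrow(inst$food_frequency))
    freq <- ifelse(is_cond, NA_integer_,
                   vapply(n_freq, function(k) sample.int(k, 1), integer(1)))
    rows[[s]] <- tibble::tibble(
      subject_id = sid,
      item_id = foods$item_id,
      freq_opt = as.integer(freq),
      amount_opt = sample.int(3, nrow(foods), replace = TRUE),
      cond_frac_opt = ifelse(is_cond,
                             sample.int(5, nrow(foods), replace = TRUE),
                             NA_integer_)
    )
  }
  dplyr::bind_rows(rows)
}
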