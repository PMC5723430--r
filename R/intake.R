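#' Recompute dietary energy from macronutrients
#'
#' Energy is always derived from the macronutrient content rather than read
#' from a composition database, because tabulated energy values are often
#' inconsistent with the tabulated macronutrients. The conversion uses
#' 0.017 MJ per gram of carbohydrate or protein and 0.037 MJ per gram of
#' fat:
#'
#' \deqn{E \,[\mathrm{MJ}] = 0.017\,(g_{carb} + g_{protein}) + 0.037\, g_{fat}}
#'
#' The function is linear, so it applies equally to per-100 g composition
#' values and to per-day intake totals.
#'
#' @param carb_g,protein_g,fat_g Grams of carbohydrate, protein and fat
#'   (vectors recycle as usual).
#' @return Energy in megajoules.
#' @examples
#' recompute_energy(100, 0, 0) # 1.7 MJ
#' recompute_energy(10, 5, 4)  # 0.403 MJ
#' @export
recompute_energy <- function(carb_g, protein_g, fat_g) {
  if (any(carb_g < 0, na.rm = TRUE) || any(protein_g < 0, na.rm = TRUE) ||
      any(fat_g < 0, na.rm = TRUE)) {
    abort("macronutrient masses must be non-negative.")
  }
  0.017 * (carb_g + protein_g) + 0.037 * fat_g
}

# times-per-month midpoint for each response row, given item kind.
# Condiments inherit the attached main item's frequency.
freq_times_per_month <- function(responses, foods, instrument) {
  kind <- foods$kind[match(responses$item_id, foods$item_id)]
  tpm <- rep(NA_real_, nrow(responses))
  is_bev <- kind == "beverage"
  is_food <- kind == "food"
  tpm[is_food] <- instrument$food_frequency$times_per_month[responses$freq_opt[is_food]]
  tpm[is_bev] <- instrument$beverage_frequency$times_per_month[responses$freq_opt[is_bev]]

  is_cond <- kind == "condiment"
  if (any(is_cond)) {
    main_id <- foods$attached_to[match(responses$item_id[is_cond], foods$item_id)]
    key <- paste(responses$subject_id, responses$item_id)
    main_idx <- match(paste(responses$subject_id[is_cond], main_id), key)
    if (anyNA(main_idx)) {
      bad <- which(is_cond)[is.na(main_idx)][1]
      abort(sprintf(
        "condiment %s (subject %s): no response for its main item %s.",
        responses$item_id[bad], responses$subject_id[bad],
        main_id[is.na(main_idx)][1]))
    }
    main_tpm <- tpm[main_idx]
    if (anyNA(main_tpm)) {
      bad <- which(is_cond)[is.na(main_tpm)][1]
      abort(sprintf(
        "condiment %s (subject %s): frequency of its main item is missing.",
        responses$item_id[bad], responses$subject_id[bad]))
    }
    frac <- instrument$condiment_fraction$fraction[responses$cond_frac_opt[is_cond]]
    tpm[is_cond] <- frac * main_tpm
  }
  tpm
}

#' Convert responses to grams per day
#'
#' Each food or beverage contributes
#' `times_per_month(freq option) * grams_per_serving(amount option) /
#' days_per_month` grams per day. A condiment contributes
#' `fraction(condiment option) * times_per_month(main item's freq option) *
#' grams_per_serving / days_per_month`, i.e. it rides on the frequency of
#' the food it is added to.
#'
#' Responses must be complete (run [impute_responses()] first): a missing
#' applicable answer is an error, never a silent zero.
#'
#' @param responses A complete response tibble.
#' @param foods A `food_table`.
#' @param instrument An `ffq_instrument`.
#' @return A tibble `subject_id`, `item_id`, `grams_per_day`.
#' @export
grams_per_day <- function(responses, foods, instrument) {
  validate_responses(responses, foods, instrument)
  kind <- foods$kind[match(responses$item_id, foods$item_id)]
  need_freq <- kind != "condiment"
  need_frac <- kind == "condiment"
  inc <- (need_freq & is.na(responses$freq_opt)) |
    (need_frac & is.na(responses$cond_frac_opt)) |
    is.na(responses$amount_opt)
  if (any(inc)) {
    r <- responses[inc, ][1, ]
    abort(sprintf(
      "incomplete response for subject %s item %s; impute before scoring.",
      r$subject_id, r$item_id))
  }
  tpm <- freq_times_per_month(responses, foods, instrument)
  fi <- match(responses$item_id, foods$item_id)
  serv <- cbind(foods$serv_small_g[fi], foods$serv_med_g[fi],
                foods$serv_large_g[fi])[cbind(seq_len(nrow(responses)),
                                              responses$amount_opt)]
  tibble(
    subject_id = responses$subject_id,
    item_id = responses$item_id,
    grams_per_day = tpm * serv / instrument$days_per_month
  )
}

NUTRIENT_COLS <- c("energy_MJ", "carb_g", "protein_g", "fat_g", "sugars_g",
                   "fiber_g", "sodium_mg")

#' Score intake profiles from FFQ responses
#'
#' The central scoring step: converts complete responses to grams/day,
#' accumulates the seven tracked quantities (energy and six nutrients) by
#' NOVA group and subgroup, recomputes total energy from the macronutrient
#' totals, and derives each subject's percent of energy by NOVA group —
#' in particular `pei_upf`, the percent of energy intake from
#' ultra-processed (group 4) foods.
#'
#' @param responses A complete response tibble.
#' @param foods A `food_table`.
#' @param instrument An `ffq_instrument`.
#' @return An `intake_profiles` object: a list of tibbles
#'   \describe{
#'     \item{per_item}{subject x item grams/day}
#'     \item{by_group}{subject x NOVA group daily nutrient totals}
#'     \item{by_subgroup}{subject x NOVA subgroup (all 33, zero-filled)}
#'     \item{pei}{subject x group percent of energy}
#'     \item{subjects}{per-subject totals, energy in MJ and kcal, and
#'       `pei_upf`}
#'   }
#'   `tidy()` on the result returns the `subjects` table.
#' @export
score_intake <- function(responses, foods, instrument) {
  validate_food_table(foods)
  per_item <- grams_per_day(responses, foods, instrument)
  fi <- match(per_item$item_id, foods$item_id)
  intake <- per_item %>%
    mutate(
      nova_group = foods$nova_group[fi],
      nova_subgroup = foods$nova_subgroup[fi],
      carb_g = .data$grams_per_day * foods$carb_g[fi] / 100,
      protein_g = .data$grams_per_day * foods$protein_g[fi] / 100,
      fat_g = .data$grams_per_day * foods$fat_g[fi] / 100,
      sugars_g = .data$grams_per_day * foods$sugars_g[fi] / 100,
      fiber_g = .data$grams_per_day * foods$fiber_g[fi] / 100,
      sodium_mg = .data$grams_per_day * foods$sodium_mg[fi] / 100,
      energy_MJ = recompute_energy(.data$carb_g, .data$protein_g, .data$fat_g)
    )

  subjects_all <- distinct(per_item["subject_id"])

  sum_by <- function(dat, key_tbl) {
    sums <- dat %>%
      group_by(across(all_of(c("subject_id", names(key_tbl))))) %>%
      summarise(across(all_of(NUTRIENT_COLS), sum), .groups = "drop")
    # complete over every subject x key so absent groups are explicit zeros
    grid <- tidyr::crossing(subjects_all, key_tbl)
    left_join(grid, sums, by = names(grid)) %>%
      mutate(across(all_of(NUTRIENT_COLS), ~ tidyr::replace_na(.x, 0)))
  }
  by_group <- sum_by(intake, tibble(nova_group = 1:4))
  by_subgroup <- sum_by(
    intake %>% select(-"nova_group"),
    nova_subgroups()["nova_subgroup"]
  ) %>%
    left_join(nova_subgroups(), by = "nova_subgroup") %>%
    select("subject_id", "nova_group", "nova_subgroup",
           all_of(NUTRIENT_COLS))

  subjects <- by_group %>%
    group_by(.data$subject_id) %>%
    summarise(across(all_of(NUTRIENT_COLS), sum), .groups = "drop") %>%
    mutate(energy_kcal = .data$energy_MJ * KCAL_PER_MJ)

  zero <- subjects$subject_id[subjects$energy_MJ <= 0]
  if (length(zero) > 0) {
    abort(sprintf("zero total energy intake for subject(s): %s",
                  paste(zero, collapse = ", ")))
  }

  pei <- by_group %>%
    left_join(subjects %>% select("subject_id", total_MJ = "energy_MJ"),
              by = "subject_id") %>%
    transmute(.data$subject_id, .data$nova_group,
              percent_energy = 100 * .data$energy_MJ / .data$total_MJ)

  subjects <- subjects %>%
    left_join(pei %>% filter(.data$nova_group == 4L) %>%
                select("subject_id", pei_upf = "percent_energy"),
              by = "subject_id")

  structure(
    list(per_item = per_item, by_group = by_group, by_subgroup = by_subgroup,
         pei = pei, subjects = subjects),
    class = "intake_profiles"
  )
}

#' @export
print.intake_profiles <- function(x, ...) {
  cat(sprintf("<intake_profiles: %d subjects, %d items>\n",
              nrow(x$subjects), length(unique(x$per_item$item_id))))
  cat(sprintf("  mean energy %.2f MJ/day, mean PEI-UPF %.1f%%\n",
              mean(x$subjects$energy_MJ), mean(x$subjects$pei_upf)))
  invisible(x)
}

#' @rdname score_intake
#' @param x An `intake_profiles` object.
#' @param ... Unused.
#' @export
tidy.intake_profiles <- function(x, ...) x$subjects

#' Cohort nutrient shares by NOVA group
#'
#' Tabulates, for each NOVA group and in total, the cohort mean absolute
#' energy intake (MJ/day) and the percent of total intake of carbohydrate,
#' protein, fat, total sugars, fiber and sodium attributable to the group.
#'
#' Two percent conventions are available. `"cohort_sum"` (default) divides
#' the cohort-wide sum of a group's nutrient by the cohort-wide total — an
#' exact additive decomposition whose four group entries sum to 100.
#' `"subject_mean"` averages each subject's own group share instead.
#'
#' @param profiles An `intake_profiles` object from [score_intake()].
#' @param method `"cohort_sum"` or `"subject_mean"`.
#' @return A tibble with rows for groups 1--4 plus `TOTAL`, columns
#'   `energy_mj_day` (mean absolute) and `<nutrient>_pct` shares.
#' @export
group_share_table <- function(profiles, method = c("cohort_sum", "subject_mean")) {
  method <- arg_match(method)
  if (nrow(profiles$subjects) == 0) abort("empty cohort.")
  share_cols <- setdiff(NUTRIENT_COLS, "energy_MJ")
  cols <- c("energy_MJ", share_cols)

  if (method == "cohort_sum") {
    grp <- profiles$by_group %>%
      group_by(.data$nova_group) %>%
      summarise(across(all_of(cols), sum), .groups = "drop")
    shares <- grp %>%
      mutate(across(all_of(cols), ~ 100 * .x / sum(.x), .names = "{.col}_pct"))
  } else {
    per_subj <- profiles$by_group %>%
      left_join(profiles$subjects %>%
                  select("subject_id", all_of(setNames(cols, paste0("tot_", cols)))),
                by = "subject_id")
    for (cc in cols) {
      per_subj[[paste0(cc, "_share")]] <-
        100 * per_subj[[cc]] / per_subj[[paste0("tot_", cc)]]
    }
    shares <- per_subj %>%
      group_by(.data$nova_group) %>%
      summarise(
        across(all_of(cols), ~ mean(.x)),
        across(all_of(paste0(cols, "_share")), ~ mean(.x)),
        .groups = "drop"
      ) %>%
      rename(!!!setNames(paste0(cols, "_share"), paste0(cols, "_pct")))
  }

  n_subj <- nrow(profiles$subjects)
  body <- shares %>%
    transmute(
      food_group = as.character(.data$nova_group),
      energy_mj_day = .data$energy_MJ / if (method == "cohort_sum") n_subj else 1,
      energy_pct = .data$energy_MJ_pct,
      carb_pct = .data$carb_g_pct,
      protein_pct = .data$protein_g_pct,
      fat_pct = .data$fat_g_pct,
      sugars_pct = .data$sugars_g_pct,
      fiber_pct = .data$fiber_g_pct,
      sodium_pct = .data$sodium_mg_pct
    )
  total <- tibble(
    food_group = "TOTAL",
    energy_mj_day = sum(body$energy_mj_day),
    energy_pct = sum(body$energy_pct),
    carb_pct = sum(body$carb_pct),
    protein_pct = sum(body$protein_pct),
    fat_pct = sum(body$fat_pct),
    sugars_pct = sum(body$sugars_pct),
    fiber_pct = sum(body$fiber_pct),
    sodium_pct = sum(body$sodium_pct)
  )
  bind_rows(body, total)
}
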