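#' NOVA subgroup catalogue
#'
#' The NOVA scheme classifies foods into four groups by the extent and
#' purpose of industrial processing; within those groups this package uses a
#' fixed catalogue of 33 nested subgroups (11 unprocessed/minimally
#' processed, 4 processed culinary ingredients, 5 processed, 13
#' ultra-processed). Every food item must carry a subgroup from this
#' catalogue, and the subgroup's parent group must match the item's
#' `nova_group`.
#'
#' @return A tibble with columns `nova_subgroup` (33 labels) and
#'   `nova_group` (1--4).
#' @export
nova_subgroups <- function() {
  tibble(
    nova_subgroup = c(
      # group 1: unprocessed or minimally processed foods
      "fruits", "vegetables", "grains", "legumes", "nuts_and_seeds",
      "meat_and_poultry", "fish_and_seafood", "eggs", "milk_and_plain_yogurt",
      "coffee_and_tea", "plain_water",
      # group 2: processed culinary ingredients
      "table_sugar_and_honey", "vegetable_oils", "butter_and_lard", "salt",
      # group 3: processed foods
      "cheese", "canned_vegetables_and_legumes", "canned_fruit",
      "cured_meats", "beer_and_wine",
      # group 4: ultra-processed foods
      "soft_drinks", "fruit_drinks", "cakes_cookies_and_pies",
      "breads", "breakfast_cereals", "salty_snacks", "candy_and_chocolate",
      "ice_cream_and_desserts", "margarine_and_spreads",
      "sauces_and_dressings", "reconstituted_meats",
      "instant_and_ready_dishes", "sweetened_dairy"
    ),
    nova_group = rep(1:4, times = c(11L, 4L, 5L, 13L))
  )
}

#' Read and join the food composition table and NOVA map
#'
#' The composition table carries one row per FFQ line item: its kind (food,
#' beverage or condiment), the grams behind each of the three portion
#' options, and nutrients per 100 g. The NOVA map assigns each item a NOVA
#' group (1--4) and one of the 33 subgroups from [nova_subgroups()]. The two
#' files must cover exactly the same item ids.
#'
#' Any energy column present in the composition file is ignored:
#' `energy_MJ_per_100g` is always recomputed from the macronutrients with
#' [recompute_energy()], because tabulated energy values are not guaranteed
#' to be consistent with the tabulated macronutrients.
#'
#' @param composition_path CSV with columns `item_id`, `name`, `kind`,
#'   `attached_to`, `serv_small_g`, `serv_med_g`, `serv_large_g`, `carb_g`,
#'   `protein_g`, `fat_g`, `sugars_g`, `fiber_g`, `sodium_mg` (nutrients per
#'   100 g; `attached_to` blank except for condiments).
#' @param nova_map_path CSV with columns `item_id`, `nova_group`,
#'   `nova_subgroup`, `note`.
#' @return A `food_table`: a tibble with one row per item, composition and
#'   classification joined, plus the derived `energy_MJ_per_100g`.
#' @export
read_food_table <- function(composition_path, nova_map_path) {
  comp_cols <- readr::cols(
    item_id = readr::col_character(),
    name = readr::col_character(),
    kind = readr::col_character(),
    attached_to = readr::col_character(),
    serv_small_g = readr::col_double(),
    serv_med_g = readr::col_double(),
    serv_large_g = readr::col_double(),
    carb_g = readr::col_double(),
    protein_g = readr::col_double(),
    fat_g = readr::col_double(),
    sugars_g = readr::col_double(),
    fiber_g = readr::col_double(),
    sodium_mg = readr::col_double()
  )
  comp <- readr::read_csv(composition_path, col_types = comp_cols)
  missing_cols <- setdiff(names(comp_cols$cols), names(comp))
  if (length(missing_cols) > 0) {
    abort(sprintf("composition table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  nova <- readr::read_csv(
    nova_map_path,
    col_types = readr::cols(
      item_id = readr::col_character(),
      nova_group = readr::col_integer(),
      nova_subgroup = readr::col_character(),
      note = readr::col_character()
    )
  )
  only_comp <- setdiff(comp$item_id, nova$item_id)
  only_nova <- setdiff(nova$item_id, comp$item_id)
  if (length(only_comp) > 0 || length(only_nova) > 0) {
    abort(sprintf(
      "composition table and NOVA map do not cover the same items.%s%s",
      if (length(only_comp)) sprintf(" Only in composition: %s.",
                                     paste(only_comp, collapse = ", ")) else "",
      if (length(only_nova)) sprintf(" Only in NOVA map: %s.",
                                     paste(only_nova, collapse = ", ")) else ""
    ))
  }
  foods <- comp %>%
    inner_join(nova, by = "item_id") %>%
    mutate(energy_MJ_per_100g = recompute_energy(.data$carb_g, .data$protein_g,
                                                 .data$fat_g))
  validate_food_table(foods)
}

#' Validate a food table
#'
#' Enforces: unique item ids; `kind` one of food/beverage/condiment; NOVA
#' group in 1--4 with a subgroup from the catalogue whose parent matches;
#' condiments (and only condiments) attached to an existing non-condiment
#' item; non-negative nutrients with carbohydrate + protein + fat at most
#' 100 g per 100 g; non-negative serving sizes.
#'
#' @param foods A food table as returned by [read_food_table()].
#' @return `foods` (with class `food_table`), invisibly usable downstream.
#' @export
validate_food_table <- function(foods) {
  dup <- foods$item_id[duplicated(foods$item_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate item ids: %s", paste(unique(dup), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(foods$kind), c("food", "beverage", "condiment"))
  if (length(bad_kind) > 0) {
    abort(sprintf("unknown item kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  if (any(!foods$nova_group %in% 1:4)) {
    abort("`nova_group` must be 1, 2, 3 or 4 for every item.")
  }
  cat_tbl <- nova_subgroups()
  unknown <- setdiff(foods$nova_subgroup, cat_tbl$nova_subgroup)
  if (length(unknown) > 0) {
    abort(sprintf("unknown NOVA subgroup(s): %s", paste(unknown, collapse = ", ")))
  }
  parent <- cat_tbl$nova_group[match(foods$nova_subgroup, cat_tbl$nova_subgroup)]
  mismatch <- foods$item_id[parent != foods$nova_group]
  if (length(mismatch) > 0) {
    abort(sprintf("subgroup's parent group does not match nova_group for: %s",
                  paste(mismatch, collapse = ", ")))
  }
  is_cond <- foods$kind == "condiment"
  if (any(is_cond & is.na(foods$attached_to))) {
    abort("every condiment must name the item it is attached to (`attached_to`).")
  }
  if (any(!is_cond & !is.na(foods$attached_to))) {
    abort("`attached_to` must be blank for non-condiments.")
  }
  mains <- foods$item_id[!is_cond]
  orphan <- foods$attached_to[is_cond][!foods$attached_to[is_cond] %in% mains]
  if (length(orphan) > 0) {
    abort(sprintf("condiments attached to unknown or condiment items: %s",
                  paste(unique(orphan), collapse = ", ")))
  }
  nutr <- c("carb_g", "protein_g", "fat_g", "sugars_g", "fiber_g", "sodium_mg",
            "serv_small_g", "serv_med_g", "serv_large_g")
  for (col in nutr) {
    if (anyNA(foods[[col]]) || any(foods[[col]] < 0)) {
      abort(sprintf("`%s` must be non-negative and non-missing.", col))
    }
  }
  over <- foods$item_id[foods$carb_g + foods$protein_g + foods$fat_g > 100 + 1e-9]
  if (length(over) > 0) {
    abort(sprintf("carb + protein + fat exceeds 100 g/100 g for: %s",
                  paste(over, collapse = ", ")))
  }
  class(foods) <- unique(c("food_table", class(foods)))
  foods
}

#' Write a food table back to its two CSV files
#'
#' Splits a joined food table into the composition CSV and the NOVA map CSV
#' accepted by [read_food_table()]; the derived energy column is not
#' written (it is always recomputed on read).
#'
#' @param foods A validated food table.
#' @param composition_path,nova_map_path Output paths.
#' @return `composition_path`, invisibly.
#' @export
write_food_table <- function(foods, composition_path, nova_map_path) {
  validate_food_table(foods)
  foods %>%
    select("item_id", "name", "kind", "attached_to", "serv_small_g",
           "serv_med_g", "serv_large_g", "carb_g", "protein_g", "fat_g",
           "sugars_g", "fiber_g", "sodium_mg") %>%
    readr::write_csv(composition_path, na = "")
  foods %>%
    mutate(note = if ("note" %in% names(foods)) .data$note else NA_character_) %>%
    select("item_id", "nova_group", "nova_subgroup", "note") %>%
    readr::write_csv(nova_map_path, na = "")
  invisible(composition_path)
}

#' The packaged example food list
#'
#' A small synthetic food list (composition values loosely modelled on
#' common US foods, spanning all four NOVA groups, all three item kinds and
#' condiment attachment) shipped with the package so that every stage of
#' the pipeline can run without external data.
#'
#' @return A `food_table`.
#' @export
default_food_table <- function() {
  read_food_table(
    system.file("extdata", "foods_composition.csv", package = "upfdiet",
                mustWork = TRUE),
    system.file("extdata", "foods_nova_map.csv", package = "upfdiet",
                mustWork = TRUE)
  )
}
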