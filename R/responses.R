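#' Read FFQ response tables
#'
#' Responses are stored long: one row per subject and line item, with the
#' chosen option *indices* (1-based positions in the instrument's ordered
#' option lists). Blank cells are genuine missing data and are kept as `NA`
#' — they are never silently treated as "never"/zero. Imputation
#' ([impute_responses()]) is the only stage that fills them.
#'
#' Which cells apply depends on the item kind: foods and beverages answer a
#' frequency option and an amount option; condiments answer a
#' condiment-fraction option and an amount option (their frequency is
#' inherited from the main item they are attached to), so their `freq_opt`
#' is structurally empty.
#'
#' @param path CSV with columns `subject_id`, `item_id`, `freq_opt`,
#'   `amount_opt`, `cond_frac_opt`.
#' @param foods,instrument Optionally, a `food_table` and `ffq_instrument`;
#'   when supplied, option indices are range-checked against them.
#' @return A tibble of responses.
#' @export
read_responses <- function(path, foods = NULL, instrument = NULL) {
  resp <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      item_id = readr::col_character(),
      freq_opt = readr::col_integer(),
      amount_opt = readr::col_integer(),
      cond_frac_opt = readr::col_integer()
    )
  )
  needed <- c("subject_id", "item_id", "freq_opt", "amount_opt", "cond_frac_opt")
  missing_cols <- setdiff(needed, names(resp))
  if (length(missing_cols) > 0) {
    abort(sprintf("response table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_responses(resp, foods, instrument)
}

#' Validate a response table
#'
#' Enforces uniqueness of (subject, item) pairs and, when `foods` and
#' `instrument` are given, that every non-missing option index is within
#' the defined range for its item kind and that condiments have no own
#' frequency answer.
#'
#' @param responses A response tibble.
#' @param foods,instrument Optional `food_table` / `ffq_instrument` for
#'   range checks.
#' @return The validated tibble.
#' @export
validate_responses <- function(responses, foods = NULL, instrument = NULL) {
  dup <- duplicated(responses[c("subject_id", "item_id")])
  if (any(dup)) {
    d <- responses[dup, c("subject_id", "item_id")][1, ]
    abort(sprintf("duplicate response rows, e.g. subject %s item %s.",
                  d$subject_id, d$item_id))
  }
  if (!is.null(foods) && !is.null(instrument)) {
    unknown <- setdiff(responses$item_id, foods$item_id)
    if (length(unknown) > 0) {
      abort(sprintf("responses reference unknown items: %s",
                    paste(unknown, collapse = ", ")))
    }
    kind <- foods$kind[match(responses$item_id, foods$item_id)]
    n_freq <- if_else(kind == "beverage",
                      nrow(instrument$beverage_frequency),
                      nrow(instrument$food_frequency))
    bad_row <- function(ok, what) {
      if (any(!ok)) {
        r <- responses[!ok, ][1, ]
        abort(sprintf("out-of-range %s for subject %s item %s.",
                      what, r$subject_id, r$item_id))
      }
    }
    f <- responses$freq_opt
    if (any(!is.na(f) & kind == "condiment")) {
      r <- responses[!is.na(f) & kind == "condiment", ][1, ]
      abort(sprintf(
        "condiment %s (subject %s) must not carry its own freq_opt.",
        r$item_id, r$subject_id))
    }
    bad_row(is.na(f) | kind == "condiment" | (f >= 1 & f <= n_freq),
            "freq_opt")
    a <- responses$amount_opt
    bad_row(is.na(a) | (a >= 1 & a <= 3), "amount_opt")
    cf <- responses$cond_frac_opt
    bad_row(is.na(cf) | (kind == "condiment" & cf >= 1 &
                           cf <= nrow(instrument$condiment_fraction)),
            "cond_frac_opt")
  }
  as_tibble(responses)
}

#' Write a response table
#'
#' Missing answers are written as blank cells, so reading the file back
#' with [read_responses()] reproduces the table exactly, missingness
#' included.
#'
#' @param responses A response tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}
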