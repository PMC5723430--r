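#' FFQ instrument definitions
#'
#' An `ffq_instrument` describes how the categorical answers on a
#' month-recall food frequency questionnaire (FFQ) map to numbers: each
#' frequency option carries a times-per-month midpoint, each condiment
#' option a fraction of the time the condiment is added to its main food.
#' Portion (amount) options are item-specific and live in the composition
#' table, not here.
#'
#' The packaged default instrument encodes the conventional completion of a
#' DHQ-II-style instrument: "never" is 0; bounded ranges take the arithmetic
#' mean of their endpoints; open-ended top categories are coded at their
#' stated bound ("2 or more times per day" as 2/day, "6 or more times per
#' day" as 6/day). All of it is overridable through the YAML file.
#'
#' @param food_frequency Data frame with columns `label`,
#'   `times_per_month`: the ordered frequency options for foods (8 options).
#' @param beverage_frequency Same shape, the ordered options for beverages
#'   ("never" through the daily top category; any count is accepted).
#' @param condiment_fraction Data frame with columns `label`, `fraction`:
#'   exactly 5 ordered options with fractions in \[0, 1\].
#' @param days_per_month Scalar used to convert per-month frequencies to
#'   per-day intakes. Default 30.4 (365.25 / 12).
#'
#' @return An object of class `ffq_instrument`.
#' @seealso [read_instrument()], [write_instrument()], [default_instrument()]
#' @export
ffq_instrument <- function(food_frequency, beverage_frequency,
                           condiment_fraction, days_per_month = 30.4) {
  x <- structure(
    list(
      food_frequency = as_tibble(food_frequency),
      beverage_frequency = as_tibble(beverage_frequency),
      condiment_fraction = as_tibble(condiment_fraction),
      days_per_month = as.numeric(days_per_month)
    ),
    class = "ffq_instrument"
  )
  validate_instrument(x)
}

#' Validate an FFQ instrument
#'
#' Checks option cardinalities ("never" plus 7 further food-frequency
#' options, exactly 5 condiment options), non-negative strictly increasing
#' frequency midpoints, zero for "never", and condiment fractions in
#' \[0, 1\].
#'
#' @param x An `ffq_instrument`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_instrument <- function(x) {
  if (!inherits(x, "ffq_instrument")) {
    abort("`x` must be an `ffq_instrument`.")
  }
  check_option_table <- function(tbl, value_col, what) {
    if (!all(c("label", value_col) %in% names(tbl))) {
      abort(sprintf("instrument field `%s` needs columns `label` and `%s`.",
                    what, value_col))
    }
    v <- tbl[[value_col]]
    if (anyNA(v) || any(v < 0)) {
      abort(sprintf("`%s`: midpoints must be non-negative and non-missing.", what))
    }
    if (any(diff(v) <= 0)) {
      abort(sprintf("`%s`: midpoints must be strictly increasing.", what))
    }
    invisible(tbl)
  }
  if (nrow(x$food_frequency) != 8L) {
    abort(sprintf("`food_frequency` must have exactly 8 options, got %d.",
                  nrow(x$food_frequency)))
  }
  if (nrow(x$condiment_fraction) != 5L) {
    abort(sprintf("`condiment_fraction` must have exactly 5 options, got %d.",
                  nrow(x$condiment_fraction)))
  }
  check_option_table(x$food_frequency, "times_per_month", "food_frequency")
  check_option_table(x$beverage_frequency, "times_per_month", "beverage_frequency")
  check_option_table(x$condiment_fraction, "fraction", "condiment_fraction")
  if (x$food_frequency$times_per_month[1] != 0) {
    abort("`food_frequency`: the first option (\"never\") must map to 0.")
  }
  if (x$beverage_frequency$times_per_month[1] != 0) {
    abort("`beverage_frequency`: the first option (\"never\") must map to 0.")
  }
  if (any(x$condiment_fraction$fraction > 1)) {
    abort("`condiment_fraction`: fractions must lie in [0, 1].")
  }
  if (!is.finite(x$days_per_month) || x$days_per_month <= 0) {
    abort("`days_per_month` must be a positive scalar.")
  }
  invisible(x)
}

#' Read an FFQ instrument from YAML
#'
#' The file must contain exactly the keys `days_per_month`,
#' `food_frequency`, `beverage_frequency` and `condiment_fraction`;
#' unknown keys are rejected so typos do not silently change midpoints.
#'
#' @param path Path to an instrument YAML file.
#' @return An `ffq_instrument`.
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) abort(sprintf("instrument file not found: %s", path))
  raw <- yaml::read_yaml(path)
  expected <- c("days_per_month", "food_frequency", "beverage_frequency",
                "condiment_fraction")
  extra <- setdiff(names(raw), expected)
  if (length(extra) > 0) {
    abort(sprintf("unknown instrument keys: %s", paste(extra, collapse = ", ")))
  }
  missing_keys <- setdiff(expected, names(raw))
  if (length(missing_keys) > 0) {
    abort(sprintf("instrument file lacks keys: %s",
                  paste(missing_keys, collapse = ", ")))
  }
  opt_tbl <- function(entries, value_col, what) {
    bad <- vapply(entries, function(e) {
      !is.list(e) || !all(c("label", value_col) %in% names(e))
    }, logical(1))
    if (any(bad)) {
      abort(sprintf("`%s`: every option needs `label` and `%s`.", what, value_col))
    }
    tibble(
      label = vapply(entries, function(e) as.character(e$label), character(1)),
      value = vapply(entries, function(e) as.numeric(e[[value_col]]), numeric(1))
    ) %>% setNames(c("label", value_col))
  }
  ffq_instrument(
    food_frequency = opt_tbl(raw$food_frequency, "times_per_month", "food_frequency"),
    beverage_frequency = opt_tbl(raw$beverage_frequency, "times_per_month",
                                 "beverage_frequency"),
    condiment_fraction = opt_tbl(raw$condiment_fraction, "fraction",
                                 "condiment_fraction"),
    days_per_month = raw$days_per_month
  )
}

#' Write an FFQ instrument to YAML
#'
#' Inverse of [read_instrument()]: `read_instrument(write_instrument(x, p))`
#' reproduces `x` exactly.
#'
#' @param x An `ffq_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(x, path) {
  validate_instrument(x)
  as_entries <- function(tbl, value_col) {
    lapply(seq_len(nrow(tbl)), function(i) {
      out <- list(tbl$label[i], tbl[[value_col]][i])
      names(out) <- c("label", value_col)
      out
    })
  }
  yaml::write_yaml(
    list(
      days_per_month = x$days_per_month,
      food_frequency = as_entries(x$food_frequency, "times_per_month"),
      beverage_frequency = as_entries(x$beverage_frequency, "times_per_month"),
      condiment_fraction = as_entries(x$condiment_fraction, "fraction")
    ),
    path,
    precision = 15
  )
  invisible(path)
}

#' The packaged default FFQ instrument
#'
#' @return An `ffq_instrument` read from the YAML file shipped in
#'   `inst/extdata/instrument.yaml`.
#' @export
default_instrument <- function() {
  read_instrument(system.file("extdata", "instrument.yaml",
                              package = "upfdiet", mustWork = TRUE))
}

#' @export
print.ffq_instrument <- function(x, ...) {
  cat("<ffq_instrument>\n")
  cat(sprintf("  food frequency options:     %d (%s ... %s)\n",
              nrow(x$food_frequency),
              x$food_frequency$label[1],
              x$food_frequency$label[nrow(x$food_frequency)]))
  cat(sprintf("  beverage frequency options: %d\n", nrow(x$beverage_frequency)))
  cat(sprintf("  condiment fraction options: %d\n", nrow(x$condiment_fraction)))
  cat(sprintf("  days per month:             %g\n", x$days_per_month))
  invisible(x)
}
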