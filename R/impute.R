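# Wide option-index representation used by the imputer: one row per subject,
# one column per applicable (item, field) pair. Structural blanks (e.g. a
# condiment's own frequency) are not columns at all, so every NA in the wide
# matrix is genuine missing data.
responses_to_wide <- function(responses, foods) {
  spec <- bind_rows(
    foods %>% filter(.data$kind != "condiment") %>%
      transmute(.data$item_id, fields = "freq_opt"),
    foods %>% filter(.data$kind == "condiment") %>%
      transmute(.data$item_id, fields = "cond_frac_opt"),
    foods %>% transmute(.data$item_id, fields = "amount_opt")
  )
  long <- responses %>%
    tidyr::pivot_longer(c("freq_opt", "amount_opt", "cond_frac_opt"),
                        names_to = "fields", values_to = "value") %>%
    inner_join(spec, by = c("item_id", "fields")) %>%
    mutate(variable = paste(.data$item_id, .data$fields, sep = "."))
  wide <- long %>%
    select("subject_id", "variable", "value") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  wide
}

wide_to_responses <- function(wide, template) {
  long <- wide %>%
    tidyr::pivot_longer(-"subject_id", names_to = "variable",
                        values_to = "value") %>%
    tidyr::separate("variable", into = c("item_id", "fields"), sep = "\\.",
                    extra = "merge")
  out <- template
  for (field in c("freq_opt", "amount_opt", "cond_frac_opt")) {
    vals <- long %>% filter(.data$fields == field)
    idx <- match(paste(out$subject_id, out$item_id),
                 paste(vals$subject_id, vals$item_id))
    got <- vals$value[idx]
    out[[field]] <- ifelse(is.na(got), out[[field]], as.integer(got))
  }
  out
}

col_mode <- function(v) {
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)]) # ties: lowest category index
}

#' Iterative random-forest imputation of FFQ responses
#'
#' Fills missing categorical answers (frequency, amount and
#' condiment-fraction option indices) by iterative imputation with an
#' ensemble of randomized decision trees, the scheme popularised by the
#' missForest algorithm: missing cells are initialised with the column
#' mode; variables are visited in order of increasing missingness; for each
#' variable a random forest is trained on the rows where it is observed
#' (all other variables, in their current imputed state, as predictors) and
#' its missing rows are predicted by majority vote (ties broken toward the
#' lowest option index); sweeps repeat until the proportion of imputed
#' cells that changed increases from one sweep to the next, at which point
#' the previous sweep's result is returned.
#'
#' Observed answers are never modified, and imputed values are always drawn
#' from the variable's observed category set. With a fixed `seed` the
#' completed table is bit-identical across runs.
#'
#' @param responses A response tibble, possibly with missing answers.
#' @param foods The `food_table` (needed to know which answers apply to
#'   which item kind).
#' @param seed Integer seed governing all forest randomness. Required.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param num_trees Trees per forest (default 100).
#' @return An `imputation_result`: list with `responses` (completed
#'   tibble), `oob` (per-variable tibble: `variable`, `n_missing`,
#'   `oob_error` — out-of-bag classification error of the final forest),
#'   `n_iter`, `converged`. `tidy()` returns the `oob` table.
#' @export
impute_responses <- function(responses, foods, seed, max_iter = 10,
                             num_trees = 100) {
  if (missing(seed) || !is.finite(seed)) abort("an integer `seed` is required.")
  validate_responses(responses, foods)
  wide <- responses_to_wide(responses, foods)
  vars <- setdiff(names(wide), "subject_id")
  mat <- as.data.frame(wide[vars])

  n_missing <- vapply(mat, function(v) sum(is.na(v)), integer(1))
  if (any(n_missing == nrow(mat))) {
    abort(sprintf("column(s) with no observed values: %s",
                  paste(vars[n_missing == nrow(mat)], collapse = ", ")))
  }

  oob <- tibble(variable = vars, n_missing = unname(n_missing),
                oob_error = NA_real_)
  if (sum(n_missing) == 0) {
    return(structure(
      list(responses = as_tibble(responses), oob = oob, n_iter = 0L,
           converged = TRUE),
      class = "imputation_result"
    ))
  }

  miss_idx <- lapply(mat, function(v) which(is.na(v)))
  # mode initialisation
  for (v in vars[n_missing > 0]) {
    mat[[v]][miss_idx[[v]]] <- col_mode(mat[[v]])
  }
  visit <- vars[n_missing > 0][order(n_missing[n_missing > 0])]

  prev_mat <- NULL
  prev_oob <- oob
  prev_change <- Inf
  n_iter <- 0L
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    before <- mat
    for (vi in seq_along(visit)) {
      v <- visit[vi]
      rows_na <- miss_idx[[v]]
      obs <- setdiff(seq_len(nrow(mat)), rows_na)
      y_obs <- mat[[v]][obs]
      y <- factor(y_obs, levels = as.character(sort(unique(y_obs))))
      if (nlevels(y) < 2) {
        mat[[v]][rows_na] <- as.integer(as.character(y[1]))
        oob$oob_error[oob$variable == v] <- 0
        next
      }
      x_cols <- setdiff(vars, v)
      fit <- ranger::ranger(
        x = mat[obs, x_cols, drop = FALSE], y = y,
        num.trees = num_trees, probability = TRUE,
        seed = (seed + 7919L * iter + vi) %% .Machine$integer.max,
        num.threads = 1
      )
      pr <- predict(fit, mat[rows_na, x_cols, drop = FALSE],
                    num.threads = 1)$predictions
      pick <- max.col(pr, ties.method = "first") # columns are sorted levels
      mat[[v]][rows_na] <- as.integer(colnames(pr)[pick])
      oob$oob_error[oob$variable == v] <- fit$prediction.error
    }
    n_iter <- iter
    n_imp <- sum(n_missing)
    changed <- sum(vapply(visit, function(v) {
      sum(mat[[v]][miss_idx[[v]]] != before[[v]][miss_idx[[v]]])
    }, numeric(1)))
    change <- changed / n_imp
    if (change > prev_change) {
      mat <- prev_mat # change metric rose: keep the previous iterate
      oob <- prev_oob
      converged <- TRUE
      break
    }
    prev_mat <- mat
    prev_oob <- oob
    if (change == 0) {
      converged <- TRUE
      break
    }
    prev_change <- change
  }

  wide[vars] <- mat
  structure(
    list(responses = wide_to_responses(wide, responses), oob = oob,
         n_iter = n_iter, converged = converged),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result: %d cells imputed across %d variables, %d sweep(s)%s>\n",
              sum(x$oob$n_missing), sum(x$oob$n_missing > 0), x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @rdname impute_responses
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @export
tidy.imputation_result <- function(x, ...) x$oob

#' Mode imputation baseline
#'
#' Fills every missing answer with its column mode (ties toward the lowest
#' option index). Used as the reference the forest imputer must beat.
#'
#' @inheritParams impute_responses
#' @return A completed response tibble.
#' @export
impute_mode <- function(responses, foods) {
  validate_responses(responses, foods)
  wide <- responses_to_wide(responses, foods)
  vars <- setdiff(names(wide), "subject_id")
  for (v in vars) {
    if (all(is.na(wide[[v]]))) {
      abort(sprintf("column with no observed values: %s", v))
    }
    wide[[v]][is.na(wide[[v]])] <- col_mode(wide[[v]])
  }
  wide_to_responses(wide, responses)
}
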