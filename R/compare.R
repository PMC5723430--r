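#' Compare two dietary indices as predictors of an outcome
#'
#' Fits the fully adjusted model once per index, reports each model's
#' adjusted R-squared, and tests whether adding the second index to the
#' first index's model significantly improves fit with an extra
#' sum-of-squares F-test:
#' \deqn{F = \frac{(RSS_{reduced} - RSS_{full})/\Delta df}{RSS_{full}/df_{full}}}
#'
#' The direction matters — the reduced model is always the `index_a`
#' model — so swapping the two indices swaps which model the F-test
#' augments.
#'
#' @param data A cohort data frame.
#' @param outcome Name of the outcome column.
#' @param index_a,index_b Names of the two dietary-index columns.
#' @param covariates Adjustment covariates shared by both models.
#' @param forced_a,forced_b Additional terms (typically interactions with
#'   the index) forced into the respective index's model.
#' @return An `index_comparison`: one-row tibble with `outcome`, `index_a`,
#'   `adj_r2_a`, `index_b`, `adj_r2_b`, `f_statistic`, `df1`, `df2`,
#'   `p_value` (for adding `index_b`'s main term to the `index_a` model).
#' @export
compare_indices <- function(data, outcome, index_a, index_b, covariates,
                            forced_a = character(), forced_b = character()) {
  check_complete(data, c(outcome, index_a, index_b, covariates,
                         forced_a, forced_b))
  fit_a <- lm(build_formula(outcome, c(index_a, covariates, forced_a)),
              data = data)
  fit_b <- lm(build_formula(outcome, c(index_b, covariates, forced_b)),
              data = data)
  check_rank(fit_a)
  check_rank(fit_b)
  fit_union <- lm(build_formula(outcome, c(index_a, covariates, forced_a,
                                           index_b)), data = data)
  alias <- names(coef(fit_union))[is.na(coef(fit_union))]
  if (length(setdiff(alias, index_b)) > 0) check_rank(fit_union)
  rss_red <- sum(residuals(fit_a)^2)
  rss_full <- sum(residuals(fit_union)^2)
  df1 <- fit_a$df.residual - fit_union$df.residual
  df2 <- fit_union$df.residual
  # index_b adds nothing the reduced model does not already span
  if (index_b %in% alias || df1 == 0) {
    f_stat <- 0
    df1 <- 0L
    p_val <- 1
  } else {
    f_stat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
    p_val <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  out <- tibble(
    outcome = outcome,
    index_a = index_a,
    adj_r2_a = summary(fit_a)$adj.r.squared,
    index_b = index_b,
    adj_r2_b = summary(fit_b)$adj.r.squared,
    f_statistic = f_stat,
    df1 = df1,
    df2 = df2,
    p_value = p_val
  )
  class(out) <- c("index_comparison", class(out))
  out
}

#' P-values of single-index models across outcomes
#'
#' For every (dietary index, outcome) pair, fits the adjusted model
#' containing that index as the only dietary predictor and extracts the
#' two-sided p-value of the index term. Neonatal outcomes additionally
#' adjust for the gestational age at which the measurement was taken.
#'
#' @param data A cohort data frame.
#' @param indices Character vector of dietary-index column names (e.g.
#'   `c("pei_upf", "hei2010", "energy_kcal_per_day", "fat_g_per_day")`).
#' @param outcomes Character vector of outcome column names.
#' @param covariates Adjustment covariates common to all models.
#' @param neonatal_outcomes Subset of `outcomes` that also adjust for
#'   `gest_age_col`.
#' @param gest_age_col Column holding gestational age at neonatal
#'   measurement (default `"gestational_age_at_measure"`).
#' @return A tibble `index` x `outcome` with `p_value` of the index term,
#'   long format.
#' @export
single_index_pvalues <- function(data, indices, outcomes, covariates,
                                 neonatal_outcomes = character(),
                                 gest_age_col = "gestational_age_at_measure") {
  grid <- tidyr::expand_grid(index = indices, outcome = outcomes)
  purrr::pmap(grid, function(index, outcome) {
    covs <- covariates
    if (outcome %in% neonatal_outcomes) covs <- c(covs, gest_age_col)
    fit <- lm(build_formula(outcome, c(index, covs)), data = data)
    check_rank(fit)
    sm <- summary(fit)$coefficients
    tibble(index = index, outcome = outcome,
           estimate = sm[index, "Estimate"],
           p_value = sm[index, "Pr(>|t|)"])
  }) %>% bind_rows()
}
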