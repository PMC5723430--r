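term_label <- function(a, b) paste(a, b, sep = ":")

build_formula <- function(outcome, terms) {
  stats::reformulate(termlabels = terms, response = outcome)
}

check_complete <- function(data, cols) {
  used <- unique(unlist(strsplit(cols, ":", fixed = TRUE)))
  used <- intersect(used, names(data))
  cc <- complete.cases(data[used])
  if (!all(cc)) {
    abort(sprintf("missing values in modelling columns (%d row(s) affected).",
                  sum(!cc)))
  }
  invisible(data)
}

check_rank <- function(fit) {
  if (fit$rank < ncol(model.matrix(fit))) {
    alias <- colnames(model.matrix(fit))[is.na(coef(fit))]
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(alias, collapse = ", ")))
  }
  if (fit$df.residual <= 0) abort("zero residual degrees of freedom.")
  invisible(fit)
}

#' Screen candidate interactions against a base model
#'
#' Each candidate interaction is tested *one at a time*: it is added to the
#' same base design (intercept, focal term, covariates and any forced
#' interactions) and retained if the extra sum-of-squares test for the
#' added term is significant at `alpha` (for a single-degree-of-freedom
#' term this is the usual two-sided t-test). Because every candidate is
#' judged against the same base, the result does not depend on the order
#' in which candidates are listed.
#'
#' @param data A cohort data frame.
#' @param outcome Name of the outcome column.
#' @param focal Name of the focal predictor (e.g. `"pei_upf"`).
#' @param covariates Character vector of adjustment covariates.
#' @param candidates Character vector of candidate interaction terms, each
#'   of the form `"a:b"`.
#' @param forced Character vector of interaction terms always kept in the
#'   base design.
#' @param alpha Two-sided significance level for retention (default 0.05).
#' @return A tibble with one row per candidate: `term`, `statistic` (F),
#'   `df`, `p_value`, `retained`.
#' @export
screen_interactions <- function(data, outcome, focal, covariates,
                                candidates, forced = character(),
                                alpha = 0.05) {
  base_terms <- c(focal, covariates, forced)
  check_complete(data, c(outcome, base_terms, candidates))
  base_fit <- lm(build_formula(outcome, base_terms), data = data)
  check_rank(base_fit)
  rows <- purrr::map(candidates, function(cand) {
    full_fit <- lm(build_formula(outcome, c(base_terms, cand)), data = data)
    check_rank(full_fit)
    cmp <- anova(base_fit, full_fit)
    tibble(term = cand,
           statistic = cmp$F[2],
           df = cmp$Df[2],
           p_value = cmp$`Pr(>F)`[2])
  })
  bind_rows(rows) %>% mutate(retained = .data$p_value < alpha)
}

#' Fit an ANCOVA-style outcome model
#'
#' Ordinary least squares of a continuous outcome on a focal dietary
#' predictor, adjustment covariates, forced interaction terms, and those
#' candidate interactions that survive screening
#' ([screen_interactions()]). This is the modelling pattern used
#' throughout: the focal-by-weight-status interaction can be forced in
#' (giving the lean and obese groups separate slopes and intercepts) while
#' other focal interactions are kept only if significant.
#'
#' Coefficients are reported with t-based Wald confidence intervals at
#' `level` and two-sided p-values. Predictors enter uncentered by default;
#' set `center = TRUE` to mean-center continuous terms before interactions
#' are formed.
#'
#' @inheritParams screen_interactions
#' @param forced Interactions always included (default none).
#' @param candidates Interactions screened at `alpha` (default none).
#' @param level Confidence level for coefficient intervals (default 0.95).
#' @param center Mean-center continuous predictor columns first?
#' @return An `ancova_fit` object. `tidy()` gives the coefficient table
#'   (`term`, `estimate`, `conf.low`, `conf.high`, `p_value`), `glance()`
#'   the fit summary (`r.squared`, `adj.r.squared`, `sigma`, `df.residual`,
#'   `n`), `autoplot()` residual diagnostic panels, and
#'   [diagnose_fit()] the formal diagnostic tests.
#' @export
fit_ancova <- function(data, outcome, focal, covariates,
                       forced = character(), candidates = character(),
                       alpha = 0.05, level = 0.95, center = FALSE) {
  data <- as_tibble(data)
  all_cols <- unique(unlist(strsplit(c(outcome, focal, covariates, forced,
                                       candidates), ":", fixed = TRUE)))
  check_complete(data, all_cols)
  if (center) {
    for (col in setdiff(intersect(all_cols, names(data)), outcome)) {
      if (is.numeric(data[[col]])) data[[col]] <- data[[col]] - mean(data[[col]])
    }
  }
  screening <- NULL
  retained <- character()
  if (length(candidates) > 0) {
    screening <- screen_interactions(data, outcome, focal, covariates,
                                     candidates, forced, alpha)
    retained <- screening$term[screening$retained]
  }
  terms <- c(focal, covariates, forced, retained)
  fit <- lm(build_formula(outcome, terms), data = data)
  check_rank(fit)
  n <- length(residuals(fit))
  if (n <= length(coef(fit)) + 1) {
    abort("too few observations for the number of model terms.")
  }
  sm <- summary(fit)
  ci <- confint(fit, level = level)
  coefs <- tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std.error = unname(sm$coefficients[, "Std. Error"]),
    statistic = unname(sm$coefficients[, "t value"]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2]),
    p_value = unname(sm$coefficients[, "Pr(>|t|)"])
  )
  structure(
    list(
      model = fit,
      outcome = outcome,
      focal = focal,
      coefficients = coefs,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      sigma = sm$sigma,
      n = n,
      design = list(covariates = covariates, forced = forced,
                    candidates = candidates, retained = retained,
                    alpha = alpha, level = level, centered = center),
      screening = screening
    ),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit: %s ~ %s + %d covariate(s)>\n", x$outcome, x$focal,
              length(x$design$covariates)))
  if (length(x$design$forced)) {
    cat("  forced interactions:  ", paste(x$design$forced, collapse = ", "), "\n")
  }
  if (length(x$design$candidates)) {
    cat("  retained from screen: ",
        if (length(x$design$retained)) paste(x$design$retained, collapse = ", ")
        else "(none)", "\n")
  }
  cat(sprintf("  n = %d, adj. R^2 = %.3f\n", x$n, x$adj_r_squared))
  foc <- x$coefficients[x$coefficients$term == x$focal, ]
  if (nrow(foc) == 1) {
    cat(sprintf("  %s: %.3g (%.3g, %.3g), p = %.3g\n", x$focal, foc$estimate,
                foc$conf.low, foc$conf.high, foc$p_value))
  }
  invisible(x)
}

#' @rdname fit_ancova
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @export
tidy.ancova_fit <- function(x, ...) x$coefficients

#' @rdname fit_ancova
#' @export
glance.ancova_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    sigma = x$sigma,
    df.residual = x$model$df.residual,
    n = x$n
  )
}

#' Residual diagnostics for an ANCOVA fit
#'
#' Formal checks of the linear-model assumptions: Shapiro-Wilk on the
#' residuals (normality); the slope of squared residuals regressed on
#' fitted values (homoscedasticity); the quadratic coefficient of
#' residuals regressed on fitted values and their square (linearity); and
#' the Durbin-Watson statistic in row order (independence /
#' first-order residual autocorrelation). Each test is flagged at
#' `alpha`; a component whose sample is too small is marked not
#' computable rather than failing the whole report.
#'
#' @param fit An `ancova_fit`.
#' @param alpha Flagging level (default 0.05).
#' @return A tibble: `test`, `statistic`, `p_value`, `computable`, `flag`.
#' @export
diagnose_fit <- function(fit, alpha = 0.05) {
  r <- residuals(fit$model)
  f <- fitted(fit$model)
  n <- length(r)
  # a numerically perfect fit has no residual structure to test
  eps <- 1e-10 * max(1, sd(f))

  row <- function(test, statistic, p_value) {
    tibble(test = test, statistic = statistic, p_value = p_value,
           computable = is.finite(p_value),
           flag = is.finite(p_value) & p_value < alpha)
  }

  normality <- if (n >= 3 && sd(r) > eps) {
    sw <- shapiro.test(r)
    row("normality_shapiro", unname(sw$statistic), sw$p.value)
  } else row("normality_shapiro", NA_real_, NA_real_)

  hetero <- if (n >= 4 && sd(f) > eps && sd(r) > eps) {
    aux <- summary(lm(I(r^2) ~ f))
    row("heteroscedasticity_sq_resid",
        aux$coefficients["f", "t value"], aux$coefficients["f", "Pr(>|t|)"])
  } else row("heteroscedasticity_sq_resid", NA_real_, NA_real_)

  linearity <- if (n >= 5 && sd(f) > eps && sd(r) > eps && sd(f^2) > eps) {
    aux <- tryCatch(summary(lm(r ~ f + I(f^2)))$coefficients,
                    error = function(e) NULL)
    if (!is.null(aux) && "I(f^2)" %in% rownames(aux) &&
        is.finite(aux["I(f^2)", "Pr(>|t|)"])) {
      row("linearity_quadratic", aux["I(f^2)", "t value"],
          aux["I(f^2)", "Pr(>|t|)"])
    } else row("linearity_quadratic", NA_real_, NA_real_)
  } else row("linearity_quadratic", NA_real_, NA_real_)

  indep <- if (n >= 6 && sd(r) > eps) {
    dw <- lmtest::dwtest(fit$model, alternative = "two.sided")
    row("independence_durbin_watson", unname(dw$statistic), dw$p.value)
  } else row("independence_durbin_watson", NA_real_, NA_real_)

  bind_rows(normality, hetero, linearity, indep)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson correlation between two continuous measures, with the
#' confidence interval obtained on the Fisher z scale
#' (`atanh(r) +- z * 1/sqrt(n - 3)`) and transformed back, and the usual
#' two-sided t-test p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 4, no missing values).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `r`, `conf.low`, `conf.high`, `p_value`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite and complete.")
  }
  n <- length(x)
  if (n < 4) abort("need at least 4 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`.")
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - level) / 2)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(
    r = r,
    conf.low = tanh(z - crit * se),
    conf.high = tanh(z + crit * se),
    p_value = 2 * pt(-abs(tstat), df = n - 2),
    n = n
  )
}
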