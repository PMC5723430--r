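#' Residual diagnostic panels for an ANCOVA fit
#'
#' Residuals against fitted values (with a horizontal reference at zero)
#' and a normal quantile-quantile panel, the two visual checks that
#' accompany [diagnose_fit()].
#'
#' @param object An `ancova_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted panels).
#' @export
autoplot.ancova_fit <- function(object, ...) {
  dat <- tibble(
    fitted = fitted(object$model),
    residual = residuals(object$model)
  )
  qq <- dat %>%
    arrange(.data$residual) %>%
    mutate(theoretical = qnorm(stats::ppoints(dplyr::n())),
           value = .data$residual, panel = "normal Q-Q")
  rf <- dat %>%
    mutate(theoretical = .data$fitted, value = .data$residual,
           panel = "residuals vs fitted")
  ggplot2::ggplot(bind_rows(rf, qq),
                  ggplot2::aes(x = .data$theoretical, y = .data$value)) +
    ggplot2::geom_hline(
      data = tibble(panel = "residuals vs fitted", y = 0),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "residual",
                  title = sprintf("%s ~ %s", object$outcome, object$focal))
}

#' Bar chart of nutrient shares by NOVA group
#'
#' @param shares A table from [group_share_table()].
#' @return A ggplot object.
#' @export
plot_group_shares <- function(shares) {
  shares %>%
    filter(.data$food_group != "TOTAL") %>%
    tidyr::pivot_longer(dplyr::ends_with("_pct"), names_to = "nutrient",
                        values_to = "percent") %>%
    mutate(nutrient = sub("_pct$", "", .data$nutrient)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$nutrient, y = .data$percent,
                                 fill = .data$food_group)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               name = "NOVA group") +
    ggplot2::labs(x = NULL, y = "% of total cohort intake")
}

#' Distribution of the ultra-processed energy share across subjects
#'
#' @param object An `intake_profiles` object.
#' @param bins Histogram bins (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intake_profiles <- function(object, bins = 15, ...) {
  ggplot2::ggplot(object$subjects, ggplot2::aes(x = .data$pei_upf)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$subjects$pei_upf),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "percent of energy from ultra-processed foods",
                  y = "subjects")
}
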