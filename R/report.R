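#' Format a two-sided p-value for reporting
#'
#' Three decimals, floored at the display threshold: values that would round
#' to 0.000 are rendered `"<0.001"`.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(round(p, 3) < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}

#' Turn an estimate into a report row
#'
#' Produces one row of the per-(locus, outcome, method) report table, with
#' both numeric columns and display strings formatted the way MR results
#' tables are usually printed: OR and `estimate (se)` to three decimals,
#' p-values floored at `"<0.001"`, and a significance flag at two-sided
#' p < 0.05.
#'
#' @param est An `mr_estimate` or `mr_egger` object.
#' @param outcome_label,locus_label Labels for the report.
#' @return A one-row tibble. For an `mr_egger` input the row describes the
#'   slope and carries the intercept estimate/p in the `egger_intercept*`
#'   columns (NA for other methods).
#' @export
to_report_row <- function(est, outcome_label, locus_label) {
  intercept <- NA_real_
  intercept_se <- NA_real_
  intercept_p <- NA_real_
  if (inherits(est, "mr_egger")) {
    intercept <- est$intercept_estimate
    intercept_se <- est$intercept_se
    intercept_p <- est$intercept_pvalue
    est <- est$slope
  }
  stopifnot(inherits(est, "mr_estimate"))
  tibble::tibble(
    locus = locus_label,
    outcome = outcome_label,
    method = est$method,
    n_variants = est$n_variants,
    estimate = est$estimate,
    se = est$se,
    ci_low = est$ci_low,
    ci_high = est$ci_high,
    pvalue = est$pvalue,
    odds_ratio = est$odds_ratio,
    or_ci_low = est$or_ci_low,
    or_ci_high = est$or_ci_high,
    egger_intercept = intercept,
    egger_intercept_se = intercept_se,
    egger_intercept_pvalue = intercept_p,
    or_display = formatC(est$odds_ratio, digits = 3, format = "f"),
    estimate_se_display = sprintf("%.3f (%.3f)", est$estimate, est$se),
    p_display = format_pvalue(est$pvalue),
    significant = est$pvalue < 0.05
  )
}

#' Scatter plot of variant associations with the fitted causal slope
#'
#' Plots variant-outcome against variant-exposure betas with per-variant
#' 95% error bars and the causal estimate as a slope through the origin
#' (plus the pleiotropy intercept for MR-Egger).
#'
#' @param instrument An `mr_harmonized` instrument.
#' @param est An `mr_estimate` or `mr_egger` to draw the slope from.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
mr_scatter <- function(instrument, est, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("mr_scatter needs the ggplot2 package", call. = FALSE)
  }
  intercept <- 0
  if (inherits(est, "mr_egger")) {
    intercept <- est$intercept_estimate
    est <- est$slope
  }
  d <- tibble::as_tibble(instrument)
  ggplot2::ggplot(d, ggplot2::aes(x = beta_x, y = beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = beta_y - .z975 * se_y,
                                        ymax = beta_y + .z975 * se_y),
                           width = 0, colour = "lightblue3") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = beta_x - .z975 * se_x,
                                         xmax = beta_x + .z975 * se_x),
                            height = 0, colour = "lightblue3") +
    ggplot2::geom_point(colour = "steelblue4") +
    ggplot2::geom_abline(intercept = intercept, slope = est$estimate,
                         colour = "darkblue") +
    ggplot2::labs(x = "variant-exposure association",
                  y = "variant-outcome association (log-odds)",
                  title = title)
}

utils::globalVariables(c("beta_x", "beta_y", "se_x", "se_y", "rsid",
                         "effect_allele", "other_allele", "se", "pvalue"))
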