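# ggplot2 figures for the main result types.

#' Pie chart of macronutrient mass shares
#'
#' One pie per recall window (and timepoint, when present), showing the
#' cohort-mean mass shares of carbohydrates, fat, protein and fiber.
#'
#' @param object An `ffq_shares` tibble from [macronutrient_shares()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ffq_shares
#' @export
autoplot.ffq_shares <- function(object, ...) {
  df <- tibble::as_tibble(object)
  grp <- intersect(c("recall_window_days", "timepoint"), names(df))
  df <- df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "nutrient")))) %>%
    dplyr::summarise(share = mean(.data$share), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$share,
                                        fill = .data$nutrient)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL, title = "Macronutrient mass shares")
  if (length(grp) > 0) {
    p <- p + ggplot2::facet_wrap(grp)
  }
  p
}

#' Heatmap of a correlation matrix
#'
#' @param object An `ffq_corr` tibble from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object (tile heatmap, one facet per stratum).
#' @method autoplot ffq_corr
#' @export
autoplot.ffq_corr <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho")
}

#' Point-range plot of test-retest reliability
#'
#' ICC(2,1) with its 95% CI per nutrient, coloured by Koo-Li class, with
#' Pearson's rho overlaid as open points.
#'
#' @param object An `ffq_reliability` tibble from [reliability_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ffq_reliability
#' @export
autoplot.ffq_reliability <- function(object, ...) {
  df <- tibble::as_tibble(object)
  facet <- intersect(c("recall_window_days", "timepoint", "pairing"),
                     names(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nutrient)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$icc2,
                                          ymin = .data$ci_lower,
                                          ymax = .data$ci_upper,
                                          colour = .data$koo_li_class)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pearson_rho), shape = 1,
                        size = 2.5) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75, 0.9), linetype = 3,
                        colour = "grey60") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "ICC(2,1) [95% CI]; open = Pearson rho",
                  x = NULL, colour = "Koo-Li")
  if (length(facet) > 0) p <- p + ggplot2::facet_wrap(facet)
  p
}

#' Intake versus dietary reference standards
#'
#' Per-metric distribution of percent-of-reference values with the 100%
#' reference line.
#'
#' @param pct A tibble from [percent_of_reference()].
#' @return A ggplot object.
#' @export
plot_percent_of_reference <- function(pct) {
  df <- pct[!is.na(pct$percent), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$percent)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "red") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "% of reference value")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
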