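#' Plot growth curves
#'
#' @param df Long growth-curve tibble.
#' @return A ggplot: OD600 vs time, one panel per species, colored by
#'   condition.
#' @export
plot_growth_curves <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$od600,
                                   color = .data$condition_id,
                                   group = interaction(.data$condition_id,
                                                       .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "time (h)", y = "OD600", color = "condition") +
    ggplot2::theme_minimal()
}

#' Plot a regularization cross-validation curve
#'
#' @param scan Output of [select_regularization()].
#' @return A ggplot of mean out-of-fold Pearson correlation vs penalty.
#' @export
plot_cv_curve <- function(scan) {
  ggplot2::ggplot(scan$curve,
                  ggplot2::aes(.data$lambda, .data$mean_oof_pearson,
                               color = .data$stage)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = scan$best_lambda, linetype = 2) +
    ggplot2::labs(x = "L1 penalty", y = "out-of-fold Pearson r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.glv_params <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$source, .data$target,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::labs(x = "source species", y = "target species",
                  fill = "a_ij") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot a simulated or measured passage series
#'
#' @param series Passage tibble (columns `passage` + species).
#' @param species Species columns; default autodetected.
#' @return A stacked-area ggplot of composition across passages.
#' @export
plot_passages <- function(series, species = NULL) {
  if (is.null(species))
    species <- setdiff(names(series), c("passage", "total_od600",
                                        "condition_id", "replicate"))
  long <- tidyr::pivot_longer(series[c("passage", species)], -"passage",
                              names_to = "species",
                              values_to = "rel_abundance")
  ggplot2::ggplot(long, ggplot2::aes(.data$passage, .data$rel_abundance,
                                     fill = .data$species)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "passage", y = "relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot a design-test-learn summary
#'
#' @param dtl Output of [run_dtl()].
#' @return A ggplot of the center-point endpoint diversity per cycle.
#' @export
plot_dtl <- function(dtl) {
  ggplot2::ggplot(dtl$summary,
                  ggplot2::aes(.data$cycle, .data$center_diversity)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "DTL cycle", y = "center-point Shannon diversity (nats)") +
    ggplot2::theme_minimal()
}
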