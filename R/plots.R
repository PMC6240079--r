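# ggplot2 displays of the synthesis results. Flux magnitudes span many
# orders of magnitude, so positive-flux panels are drawn on a log10 scale
# (the convention of cross-ecosystem boxplot figures); NEP keeps a linear
# axis because heterotrophic systems are negative.

#' Boxplots of flux magnitudes by group
#'
#' Log-scale boxplots of harmonized flux values (median, quartile box,
#' whisker range), one box per group. Non-positive values (possible for
#' NEP) are dropped from the log panel with a message.
#'
#' @param records A harmonized `flux_table`.
#' @param x Column mapped to the x axis (default `ecosystem`).
#' @param fill Optional column mapped to fill (default `flux_class`).
#' @return A ggplot object.
#' @export
plot_flux_boxplots <- function(records, x = "ecosystem", fill = "flux_class") {
  df <- tibble::as_tibble(records)
  npos <- sum(df$value <= 0)
  if (npos > 0) {
    inform(paste0("dropping ", npos, " non-positive value(s) from log-scale plot"))
    df <- df[df$value > 0, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$value,
                                   fill = .data[[fill]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = expression(gC ~ m^-2 ~ yr^-1), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.flux_table <- function(object, ...) plot_flux_boxplots(object, ...)

#' @describeIn nep_analysis NEP boxplots per ecosystem, annotated with the
#'   heterotrophy probability `p+` above and the post-hoc letter group
#'   below each box; the dashed line marks NEP = 0.
#' @param object A `crossflux_nep_analysis` object.
#' @exportS3Method ggplot2::autoplot
autoplot.crossflux_nep_analysis <- function(object, ...) {
  df <- tibble::as_tibble(object$data)
  df$ecosystem <- factor(df$ecosystem,
                         levels = intersect(flux_vocab()$ecosystem,
                                            unique(df$ecosystem)))
  ann <- object$per_ecosystem
  ypos <- max(df$value) * 1.08
  yneg <- min(df$value) * 1.08
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ecosystem, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(fill = "grey90", linewidth = 0.3,
                          outlier.size = 0.5) +
    ggplot2::annotate("text", x = ann$ecosystem, y = ypos,
                      label = sprintf("%.2f", ann$p_plus), size = 3) +
    ggplot2::annotate("text", x = ann$ecosystem, y = yneg,
                      label = ann$letters, size = 3, fontface = "italic") +
    ggplot2::labs(y = expression(NEP ~ (gC ~ m^-2 ~ yr^-1)), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Spatial-vs-local magnitude gap plot
#'
#' Dot plot of the order-of-magnitude gap `log10(median local / median
#' spatial inflow)` per recipient ecosystem, one point per (local flux
#' class, spatial origin) pair; positive values mean local fluxes dominate.
#'
#' @param comparison Output of [compare_spatial_local()].
#' @return A ggplot object.
#' @export
plot_spatial_local_gap <- function(comparison) {
  ggplot2::ggplot(
    dplyr::filter(comparison, is.finite(.data$log10_ratio)),
    ggplot2::aes(x = .data$ecosystem, y = .data$log10_ratio,
                 colour = .data$local_flux_class,
                 shape = .data$spatial_origin)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(y = "log10(local / spatial inflow)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
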