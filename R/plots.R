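# ggplot2 views of the main result types. Each returns the plot object;
# nothing is printed or written as a side effect.

#' @export
autoplot.amp_rate_test <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = stats::reorder(.data$stratum,
                                                  -.data$rate_percent),
                               y = .data$rate_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$k,
                                                    .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "amplification rate (%)",
      title = sprintf("%s amplification by %s", object$anchor,
                      paste(object$stratum_key, collapse = " x ")),
      subtitle = sprintf("%s: p = %.3g", object$test$method,
                         object$test$p_value)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Volcano plot of a differential-expression table
#'
#' @param deg Result of [differential_expression()].
#' @param log2fc_threshold,alpha Thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_deg_volcano <- function(deg, log2fc_threshold = 2, alpha = 0.05) {
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$avg_log2FC,
                                    y = -log10(.data$p_adjusted),
                                    colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2fc_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "avg_log2FC (high vs low)",
                  y = "-log10 adjusted p", colour = "pass") +
    ggplot2::theme_minimal()
}

#' Spot map of one gene's expression over a section
#'
#' @param section A [spatial_section()].
#' @param gene Gene symbol.
#' @param mask Optional [high_region_mask()] whose member spots are
#'   outlined.
#' @return A ggplot object.
#' @export
plot_spatial_gene <- function(section, gene, mask = NULL) {
  if (!gene %in% rownames(section$expr)) {
    stop_input(sprintf("gene '%s' absent from the section.", gene))
  }
  df <- dplyr::mutate(section$coords, expr = section$expr[gene, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$expr)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (%s)", gene, section$section_id),
                  colour = "expression") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$spot_id %in% mask$spots),
      shape = 21, size = 3.2, colour = "red", fill = NA
    )
  }
  p
}

#' @export
autoplot.spatial_screen <- function(object, ...) {
  df <- dplyr::filter(object$per_section, !.data$skipped)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_obs,
                                   y = -log10(.data$q),
                                   colour = .data$section_id)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("mean NN distance to %s-high region", object$anchor),
      y = "-log10 BH q (empirical p)", colour = "section"
    ) +
    ggplot2::theme_minimal()
}
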