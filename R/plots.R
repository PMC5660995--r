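#' @rdname fit_standard_curve
#' @param object A `standard_curve`.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = log10(.data$quantity), y = .data$cq)
  ) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "log10(relative input quantity)", y = "Cq (cycles)",
      title = if (is.na(object$gene_id)) "Standard curve" else
        paste("Standard curve:", object$gene_id),
      subtitle = sprintf(
        "slope %.3f, E = %.1f%%, QC %s",
        object$slope, 100 * object$efficiency,
        if (object$qc_pass) "pass" else "fail"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the stress matrix
#'
#' @param object A `stress_matrix` from [build_stress_matrix()].
#' @param ... Unused.
#' @return A ggplot object: variety x stress tiles filled by score,
#'   faceted by location; undefined cells are blank.
#' @method autoplot stress_matrix
#' @export
autoplot.stress_matrix <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(.data$stress, levels = stress_levels()),
      y = .data$variety, fill = .data$score
    )
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~location) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      x = "stress", y = "variety",
      fill = "mean |log2 ratio|\n(qualifying markers)"
    ) +
    ggplot2::theme_minimal()
}

#' Box plots of expression-ratio distributions
#'
#' The distribution of per-gene mean log2 ratios for each variety, split by
#' a-priori regulation direction and faceted by location — the standard
#' at-a-glance view of how strongly each genotype responded.
#'
#' @inheritParams build_stress_matrix
#' @return A ggplot object.
#' @export
plot_expression_distribution <- function(ratios, panel,
                                         control_ref = "tolerant_control",
                                         treatment = "stress") {
  markers <- dplyr::filter(panel, !.data$is_reference)
  df <- ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref,
      !is.na(.data$log2_mean)
    ) |>
    dplyr::inner_join(
      dplyr::select(markers, "gene_id", "expected_direction"),
      by = "gene_id"
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$variety, y = .data$log2_mean,
      fill = .data$expected_direction
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_grid(expected_direction ~ location) +
    ggplot2::labs(
      x = "variety", y = "log2(expression ratio)", fill = "a-priori"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' Bar chart of functional-bin relevance
#'
#' @param bins Output of [bin_aggregate()].
#' @return A ggplot object: mean log2 ratio per bin, split by a-priori
#'   direction and faceted by location; inverted bins are outlined.
#' @export
plot_bin_relevance <- function(bins) {
  ggplot2::ggplot(
    bins,
    ggplot2::aes(
      x = .data$mean_log2, y = .data$mapman_bin,
      fill = .data$expected_direction, colour = .data$inverted
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~location) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = NA, `TRUE` = "black")
    ) +
    ggplot2::labs(
      x = "mean log2(expression ratio)", y = "functional bin",
      fill = "a-priori", colour = "inverted"
    ) +
    ggplot2::theme_minimal()
}
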