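#' Volcano plot of a differential-expression result
#'
#' @param de A `syncom_de` object or a tidy DE tibble.
#' @param lfc_strong Absolute shrunken log2FC above which points are
#'   highlighted as strong responders (default 1.5). The DEG call itself is
#'   adjusted p below the fit's significance level.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_strong = 1.5) {
  tbl <- if (inherits(de, "syncom_de")) de$result else de
  tbl <- tbl[tbl$tested & !is.na(tbl$padj), ]
  tbl$status <- ifelse(!tbl$deg, "not DE",
                ifelse(abs(tbl$log2fc_shrunk) > lfc_strong, "DE, strong", "DE"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$log2fc_shrunk,
                                    y = -log10(pmax(.data$padj, 1e-300)),
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c("not DE" = "grey60",
                                            "DE" = "steelblue",
                                            "DE, strong" = "firebrick")) +
    ggplot2::labs(x = "shrunken log2 fold change (root vs matrix)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of RNA-based strain abundance profiles
#'
#' @param profile Abundance-profile tibble ([strain_relative_abundance()]).
#' @param samples Sample metadata tibble.
#' @return A ggplot object: per-strain mean RA by compartment, log scale.
#' @export
plot_abundance_profile <- function(profile, samples) {
  tbl <- profile |>
    dplyr::left_join(samples[, c("sample", "compartment")], by = "sample") |>
    dplyr::group_by(.data$strain_id, .data$compartment) |>
    dplyr::summarise(mean_ra = mean(.data$ra, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$strain_id, -.data$mean_ra),
                                    y = .data$mean_ra, fill = .data$compartment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname pcoa_ordination
#' @param object A `pcoa_ordination`.
#' @param units Optional unit metadata tibble (joined on `unit`) for
#'   colouring, e.g. the `units` element of [og_relative_counts()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ordination <- function(object, units = NULL, ...) {
  tbl <- object$coordinates
  if (!is.null(units)) tbl <- dplyr::left_join(tbl, units, by = "unit")
  aes <- if (!is.null(units) && "compartment" %in% names(tbl)) {
    ggplot2::aes(x = .data$axis_1, y = .data$axis_2, colour = .data$compartment)
  } else {
    ggplot2::aes(x = .data$axis_1, y = .data$axis_2)
  }
  ggplot2::ggplot(tbl, aes) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", object$variance_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", object$variance_explained[2])) +
    ggplot2::theme_minimal()
}

#' Heatmap of category-level regulation per strain
#'
#' @param cat_lfc Tibble from [category_mean_lfc()].
#' @return A ggplot tile plot of mean log2FC by strain and COG category.
#' @export
plot_category_heatmap <- function(cat_lfc) {
  ggplot2::ggplot(cat_lfc, ggplot2::aes(x = .data$cog_category,
                                        y = .data$strain_id,
                                        fill = .data$mean_log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "COG category", y = NULL, fill = "mean log2FC") +
    ggplot2::theme_minimal()
}
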