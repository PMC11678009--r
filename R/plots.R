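# ggplot2 convenience layers. These render the standard views (score plots
# with group ellipses, loading/VIP bars, enrichment dot plots, degree
# histograms, group-mean heatmaps); all analysis results stay in the tables.

#' @rdname fit_pca
#' @param data Optional metadata joined to the scores by `sample_id`.
#' @param colour Metadata column used for point colour (and ellipses).
#' @param components Which two components to plot (default `c(1, 2)`).
#' @param ellipse_level Confidence level for group ellipses; `NULL` disables.
#' @export
autoplot.metab_pca <- function(object, data = NULL, colour = "condition",
                               components = c(1, 2), ellipse_level = 0.95,
                               ...) {
  pcs <- paste0("PC", components)
  df <- tidy(object, "scores")[, c("sample_id", pcs)]
  names(df) <- c("sample_id", "x", "y")
  pct <- round(100 * object$variance_fraction[components], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  if (!is.null(data) && colour %in% names(data)) {
    df <- left_join(df, as_tibble(data), by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = factor(.data[[colour]])))
    if (!is.null(ellipse_level)) {
      ell <- group_ellipse(df[, c("x", "y")], df[[colour]],
                           level = ellipse_level)
      if (nrow(ell)) {
        paths <- purrr::map_dfr(seq_len(nrow(ell)),
                                function(i) ellipse_path(ell[i, ]))
        p <- p + ggplot2::geom_path(
          data = paths,
          ggplot2::aes(.data$x, .data$y, colour = factor(.data$group)),
          inherit.aes = FALSE, linewidth = 0.3)
      }
    }
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], pct[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], pct[2]),
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' @rdname fit_oplsda
#' @param top Number of largest-|loading| metabolites to show.
#' @export
autoplot.oplsda <- function(object, top = 25, ...) {
  df <- tidy(object)
  df <- head(arrange(df, dplyr::desc(abs(.data$loading))), top)
  df$metabolite_id <- factor(df$metabolite_id,
                             levels = rev(df$metabolite_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$loading, .data$metabolite_id,
                                   fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "predictive loading", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param result A tibble from [msea_run()].
#' @param padj_max Only sets at or below this adjusted p are shown.
#' @return A ggplot.
#' @export
plot_enrichment <- function(result, padj_max = 0.25) {
  df <- result[result$padj <= padj_max, , drop = FALSE]
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$nes, .data$set_id,
                                   size = abs(.data$nes),
                                   colour = .data$padj,
                                   shape = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(up = 24, down = 25)) +
    ggplot2::labs(x = "NES", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname degree_histogram
#' @param object A `metab_network`.
#' @param ... Unused.
#' @export
autoplot.metab_network <- function(object, ...) {
  df <- degree_histogram(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$degree, .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = object$stratum, x = "node degree", y = "count") +
    ggplot2::theme_minimal()
}

#' Heatmap of the group-mean matrix
#'
#' @param gmm Output of [group_mean_matrix()].
#' @return A ggplot tile map, metabolites in rows, groups in columns.
#' @export
plot_group_heatmap <- function(gmm) {
  long <- tidyr::pivot_longer(gmm,
                              cols = -dplyr::any_of(c("metabolite_id",
                                                      "chem_class")),
                              names_to = "group", values_to = "z")
  long$metabolite_id <- factor(long$metabolite_id,
                               levels = rev(unique(gmm$metabolite_id)))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$metabolite_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
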