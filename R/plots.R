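#' Heatmap of a Fisher-z connectivity matrix
#'
#' @param fc Matrix from [fc_matrix()].
#' @param scheme Optional scheme tibble; when given, regions are annotated
#'   by tissue class on the axes (as ordered strips).
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(fc, scheme = NULL) {
  z <- fc_as_matrix(fc)
  nm <- rownames(z) %||% as.character(seq_len(nrow(z)))
  df <- tidyr::expand_grid(row = seq_len(nrow(z)), col = seq_len(ncol(z)))
  df$z <- z[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85",
                                  name = "Fisher z") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(scheme)) {
    bounds <- cumsum(table(factor(scheme$tissue_class,
                                  levels = c("cortical", "subcortical", "wm"))))
    bounds <- bounds[-length(bounds)] + 0.5
    p <- p + ggplot2::geom_hline(yintercept = bounds, linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = bounds, linewidth = 0.2)
  }
  p
}

#' Group comparison of subject-level FCS for selected regions
#'
#' Boxplots with jittered points of FCS by group, faceted by region.
#'
#' @param fcs Subject-level FCS tibble (from [cohort_fcs()]).
#' @param records Subject tibble with `subject_id` and `group`.
#' @param regions Regions to display.
#' @return A ggplot object.
#' @export
plot_fcs_by_group <- function(fcs, records, regions) {
  d <- fcs |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::inner_join(dplyr::select(records, dplyr::all_of(c("subject_id",
                                                             "group"))),
                      by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.5) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "FCS (mean Fisher z)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}

#' Volcano-style overview of a region group test
#'
#' Group-coefficient estimates against -log10 p, faceted by FCS family,
#' with FDR-significant regions highlighted.
#'
#' @param object A `wmfcs_group_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wmfcs_group_test
#' @export
autoplot.wmfcs_group_test <- function(object, ...) {
  d <- tidy(object)
  d$significant <- !is.na(d$p.fdr) & d$p.fdr < object$alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = -log10(.data$p.value),
                                  color = .data$significant)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey55",
                                           `TRUE` = "#b2182b"),
                                name = sprintf("FDR q < %g", object$alpha)) +
    ggplot2::labs(x = "Group coefficient (post - pre, FCS units)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_bw()
}
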