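# ggplot2 views of the main result types.

#' Volcano plot of differential expression results
#'
#' @param object A `deg_stats` tibble (probe or gene level).
#' @param p_thresh,fc_thresh Thresholds drawn as dashed guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_stats
#' @export
autoplot.deg_stats <- function(object, p_thresh = 0.05, fc_thresh = 1.5,
                               ...) {
  df <- mutate(object,
               called = .data$p_adj < p_thresh & abs(.data$fc) > fc_thresh)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(.data$p_adj),
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_thresh), log2(fc_thresh)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_thresh), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p")
}

#' Volcano plot of differential methylation results
#'
#' @param object A `dmp_stats` tibble.
#' @param p_thresh,db_thresh Thresholds drawn as dashed guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmp_stats
#' @export
autoplot.dmp_stats <- function(object, p_thresh = 0.05, db_thresh = 0.12,
                               ...) {
  df <- mutate(object,
               called = .data$p_adj < p_thresh &
                 abs(.data$delta_beta) > db_thresh)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_beta, -log10(.data$p_adj),
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-db_thresh, db_thresh),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_thresh), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "navy"),
                                 guide = "none") +
    ggplot2::labs(x = "median beta difference (case - control)",
                  y = "-log10 adjusted p")
}

#' Quadrant plot of MeDEG classes
#'
#' Expression change against methylation change, one point per overlap
#' gene, coloured by direction class: inverse genes fall in the upper-left
#' and lower-right quadrants.
#'
#' @param object A `medeg_tbl` from [identify_medegs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medeg_tbl
#' @export
autoplot.medeg_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_beta, .data$log2_fc,
                                       colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "median beta difference",
                  y = "log2 fold change", colour = "class")
}

#' Per-sample LOOCV predictions of a fitted panel
#'
#' @param object A `panel_result` from [loocv_svm()] or
#'   [search_feature_panel()].
#' @param ... Unused.
#' @return A ggplot object showing each sample's predicted class against
#'   its true group.
#' @method autoplot panel_result
#' @export
autoplot.panel_result <- function(object, ...) {
  df <- mutate(object$per_sample_predictions,
               correct = .data$truth == .data$predicted)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$predicted,
                                   colour = .data$correct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$truth), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "predicted class", colour = "correct")
}

#' Bar chart of the genomic distribution of DMPs
#'
#' @param distribution Output of [summarize_genomic_distribution()].
#' @return A ggplot object with one panel per dimension.
#' @export
plot_genomic_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(.data$category, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$dimension), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of DMPs")
}
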