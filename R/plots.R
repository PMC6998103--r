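#' Plot a screening panel
#'
#' Tumor median expression against median fold change (both log10),
#' colored by strict-panel membership. The dashed guides mark the
#' cascade's tumor-median and fold-change thresholds.
#'
#' @param object A `screen_panel` from [apply_strict_criteria()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_panel
#' @export
autoplot.screen_panel <- function(object, ...) {
  crit <- attr(object, "criteria")
  df <- tidy(object) %>%
    filter(!is.na(.data$cancer_median), !is.na(.data$fold_change))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer_median, y = .data$fold_change,
                                   color = .data$strict_pass)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = crit$cancer_median_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = crit$fold_min, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "tumor median (rpkm)", y = "median fold change",
                  color = "strict panel") +
    ggplot2::theme_minimal()
}

#' Plot qPCR group-comparison results
#'
#' Signed fold change per gene, colored by verdict; genes are ordered by
#' fold change and the unit fold lines are marked.
#'
#' @param object A `qpcr_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qpcr_comparison
#' @export
autoplot.qpcr_comparison <- function(object, ...) {
  df <- tidy(object) %>%
    filter(!is.na(.data$fold_change_signed)) %>%
    mutate(gene = stats::reorder(.data$gene, .data$fold_change_signed))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$fold_change_signed,
                                   fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signed fold change (case vs baseline)",
                  fill = "verdict",
                  subtitle = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' Plot per-sample relative quantities for selected genes
#'
#' Jittered per-sample RQ values by group on a log2 axis, one facet per
#' gene — the standard view for judging dysregulation of individual
#' genes in a small qPCR cohort.
#'
#' @param rq_table A Cq tibble with an `rq` column (see
#'   [add_relative_quantity()]).
#' @param genes Optional subset of genes to show.
#' @return A ggplot object.
#' @export
plot_relative_quantities <- function(rq_table, genes = NULL) {
  if (!"rq" %in% names(rq_table)) {
    abort_validation("rq_table needs an 'rq' column; run add_relative_quantity() first")
  }
  df <- filter(rq_table, !is.na(.data$rq))
  if (!is.null(genes)) df <- filter(df, .data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$rq)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative quantity (log2 axis)") +
    ggplot2::theme_minimal()
}
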