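#' Tidiers for screening and qPCR results
#'
#' `tidy()` returns the underlying per-gene tibble; `glance()` returns a
#' one-row summary.
#'
#' For a `screen_panel`, `tidy()` binds the strict panel and the relaxed
#' remainder (strict first, each ordered by descending tumor median) and
#' `glance()` reports panel sizes plus the count of strict genes with
#' tumor median above 10 rpkm — the high-expression core of the panel.
#'
#' @param x A `screen_panel`, `gene_screen` or `qpcr_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @name rccpanel-tidiers
NULL

#' @rdname rccpanel-tidiers
#' @method tidy screen_panel
#' @export
tidy.screen_panel <- function(x, ...) {
  bind_rows(x$strict, x$relaxed)
}

#' @rdname rccpanel-tidiers
#' @method glance screen_panel
#' @export
glance.screen_panel <- function(x, ...) {
  tibble(
    n_genes = nrow(x$strict) + nrow(x$relaxed),
    n_strict = nrow(x$strict),
    n_relaxed = nrow(x$relaxed),
    n_strict_median_gt_10 = sum(x$strict$cancer_median > 10, na.rm = TRUE)
  )
}

#' @rdname rccpanel-tidiers
#' @method tidy gene_screen
#' @export
tidy.gene_screen <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname rccpanel-tidiers
#' @method glance gene_screen
#' @export
glance.gene_screen <- function(x, ...) {
  crit <- attr(x, "criteria")
  tibble(
    n_genes = nrow(x),
    n_defined = sum(x$stats_defined),
    alpha = crit$alpha,
    n_significant = sum(x$p_value < crit$alpha, na.rm = TRUE)
  )
}

#' @rdname rccpanel-tidiers
#' @method tidy qpcr_comparison
#' @export
tidy.qpcr_comparison <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname rccpanel-tidiers
#' @method glance qpcr_comparison
#' @export
glance.qpcr_comparison <- function(x, ...) {
  tibble(
    comparison = attr(x, "comparison"),
    alpha = attr(x, "alpha"),
    n_genes = nrow(x),
    n_up = sum(x$verdict == "up"),
    n_down = sum(x$verdict == "down"),
    n_ns = sum(x$verdict == "ns")
  )
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "criteria") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "comparison") <- NULL
  x
}
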