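#' Screening criteria for the candidate panel
#'
#' The threshold cascade a gene must clear to enter the strict candidate
#' panel: essentially absent from healthy blood, overexpressed in tumor
#' versus matched normal tissue, well separated between the two tissue
#' distributions, and highly expressed in tumor in absolute terms.
#'
#' @param blood_p95_max Per-source upper bounds (inclusive) on the blood
#'   95th percentile, in rpkm. A named vector is matched against the
#'   blood summary columns (e.g. `c(geo = 1, gtex = 1)`); an unnamed
#'   scalar applies to every source. Inclusive comparison is deliberate:
#'   a gene whose blood p95 sits exactly on 1 rpkm is still treated as
#'   plausibly non-expressed given RNA-seq background sensitivity.
#' @param fold_min Exclusive lower bound on the tumor/normal median fold
#'   change (default 1: any overexpression).
#' @param percentile_ratio_min Exclusive lower bound on the 5th/95th
#'   percentile-ratio distance (default 0.5).
#' @param cancer_median_min Exclusive lower bound on the tumor median,
#'   rpkm (default 5).
#' @param overlap_score_max Advisory upper bound on the overlap score
#'   (default 0.3). Reported alongside the panel; only enforced as a
#'   hard filter when `overlap_is_hard = TRUE`, since the printed strict
#'   cascade does not include it.
#' @param overlap_is_hard Promote the overlap-score bound to a hard
#'   criterion.
#' @param alpha Significance level for group-comparison verdicts
#'   (default 0.05); used in reporting and the qPCR stage, not in the
#'   strict cascade.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(blood_p95_max = c(geo = 1, gtex = 1),
                            fold_min = 1,
                            percentile_ratio_min = 0.5,
                            cancer_median_min = 5,
                            overlap_score_max = 0.3,
                            overlap_is_hard = FALSE,
                            alpha = 0.05) {
  if (any(blood_p95_max < 0) || fold_min < 0 || percentile_ratio_min < 0 ||
      cancer_median_min < 0 || overlap_score_max < 0) {
    abort_validation("screening thresholds must be nonnegative")
  }
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must lie in (0, 1)")
  structure(
    list(
      blood_p95_max = blood_p95_max,
      fold_min = fold_min,
      percentile_ratio_min = percentile_ratio_min,
      cancer_median_min = cancer_median_min,
      overlap_score_max = overlap_score_max,
      overlap_is_hard = isTRUE(overlap_is_hard),
      alpha = alpha
    ),
    class = "screen_criteria"
  )
}

#' Tissue-specific gene set by subtraction
#'
#' Conditional tissue specificity: the target tissue's enriched set
#' minus every gene that is also listed for any of the excluded tissues.
#' For kidney-cancer blood biomarkers the usual exclusion list is blood
#' plus organs with high baseline transcript leakage into blood (liver,
#' prostate, bladder).
#'
#' @param sets Named list of character vectors, as returned by
#'   [read_gene_sets()].
#' @param target Tissue whose set is filtered.
#' @param exclude Tissues to subtract; a tissue missing from `sets` is
#'   treated as an empty set with a warning.
#' @return Sorted character vector of conditionally specific symbols.
#' @examples
#' sets <- list(kidney = c("A", "B", "C"), blood = "B", bladder = "C")
#' kidney_specific_genes(sets, "kidney", c("blood", "bladder", "liver"))
#' @export
kidney_specific_genes <- function(sets, target = "kidney",
                                  exclude = c("blood", "liver", "prostate", "bladder")) {
  if (!target %in% names(sets)) {
    abort_validation(sprintf("target tissue '%s' not present in gene sets", target))
  }
  absent <- setdiff(exclude, names(sets))
  if (length(absent)) {
    warning(sprintf("exclude tissue(s) not in gene sets, treated as empty: %s",
                    oxford(absent)), call. = FALSE)
  }
  drop <- unique(unlist(sets[intersect(exclude, names(sets))], use.names = FALSE))
  sort(setdiff(sets[[target]], drop))
}

#' Per-gene blood baseline summary (95th percentiles)
#'
#' Summarizes healthy-blood expression per gene as the 95th percentile
#' of rpkm values within each source group. Sources can be grouped (for
#' example, several small GEO-style datasets pooled into one `geo` group
#' next to a large `gtex` group); within a group all samples are pooled
#' before the percentile is taken. A gene absent from a source
#' contributes zeros for that source's samples, with a warning — absence
#' from an annotation is read as non-detection, the conservative choice
#' for an absence screen.
#'
#' @param sources Named list of [expr_matrix()] objects in rpkm.
#' @param groups Optional named list mapping a group label to the source
#'   labels pooled under it; defaults to one group per source.
#' @param genes Optional gene universe; defaults to the union of gene
#'   ids over all sources.
#' @return A tibble with `gene` and one `blood_p95_<group>` column per
#'   group.
#' @export
summarize_blood <- function(sources, groups = NULL, genes = NULL) {
  if (!length(sources) || is.null(names(sources)) || any(!nzchar(names(sources)))) {
    abort_validation("sources must be a non-empty named list of rpkm matrices")
  }
  for (lab in names(sources)) {
    assert_unit(sources[[lab]], "rpkm", sprintf("blood source '%s'", lab))
  }
  if (is.null(groups)) groups <- setNames(as.list(names(sources)), names(sources))
  unknown <- setdiff(unlist(groups), names(sources))
  if (length(unknown)) {
    abort_validation(sprintf("groups refer to unknown sources: %s", oxford(unknown)))
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(sources, function(m) m$gene_id), use.names = FALSE))
  }
  cols <- lapply(names(groups), function(grp) {
    pooled <- lapply(groups[[grp]], function(lab) {
      m <- sources[[lab]]
      vals <- expr_values(m)
      idx <- match(genes, m$gene_id)
      absent <- genes[is.na(idx)]
      if (length(absent)) {
        warning(sprintf("gene(s) absent from blood source '%s', treated as 0: %s",
                        lab, oxford(absent)), call. = FALSE)
      }
      out <- vals[pmax(idx, 1L), , drop = FALSE]
      out[is.na(idx), ] <- 0
      out
    })
    pooled <- do.call(cbind, pooled)
    unname(apply(pooled, 1, pctl, q = 95))
  })
  names(cols) <- paste0("blood_p95_", names(groups))
  tibble(gene = genes, !!!cols)
}

#' Per-gene screening statistics for tumor versus normal cohorts
#'
#' Builds one record per gene carrying every screening statistic: tumor
#' median expression, median fold change, percentile-ratio distance,
#' overlap score, two-sided Mann-Whitney p-value, group sizes and (when
#' supplied) the per-source blood 95th percentiles. No filtering happens
#' here; [apply_strict_criteria()] partitions the records.
#'
#' Genes with fewer than two observations in either group get `NA`
#' statistics and `stats_defined = FALSE`; a defined-but-degenerate
#' statistic (zero normal median or zero normal 95th percentile) is
#' likewise `NA`, which downstream counts as not favorable.
#'
#' @param tumor,normal [expr_matrix()] objects in rpkm sharing one gene
#'   universe, already collapsed and per-subject averaged.
#' @param blood_p95 Optional blood summary from [summarize_blood()].
#' @param criteria A [screen_criteria()] object, attached to the result.
#' @return A tibble of class `gene_screen`, one row per gene.
#' @export
screen_genes <- function(tumor, normal, blood_p95 = NULL,
                         criteria = screen_criteria()) {
  assert_unit(tumor, "rpkm", "tumor matrix")
  assert_unit(normal, "rpkm", "normal matrix")
  if (anyDuplicated(tumor$gene_id) || anyDuplicated(normal$gene_id)) {
    abort_validation("matrices contain duplicate gene rows; run collapse_max() first")
  }
  if (!setequal(tumor$gene_id, normal$gene_id)) {
    off <- c(setdiff(tumor$gene_id, normal$gene_id), setdiff(normal$gene_id, tumor$gene_id))
    abort_validation(sprintf("tumor and normal gene universes differ: %s", oxford(off)))
  }
  tv <- expr_values(tumor)
  nv <- expr_values(normal)[match(tumor$gene_id, normal$gene_id), , drop = FALSE]
  recs <- purrr::map_dfr(seq_along(tumor$gene_id), function(i) {
    ca <- tv[i, ]
    no <- nv[i, ]
    defined <- length(ca) >= 2L && length(no) >= 2L
    if (!defined) {
      return(tibble(
        gene = tumor$gene_id[i], n_cancer = length(ca), n_normal = length(no),
        cancer_median = NA_real_, fold_change = NA_real_,
        percentile_ratio = NA_real_, overlap_score = NA_real_,
        p_value = NA_real_, stats_defined = FALSE
      ))
    }
    tibble(
      gene = tumor$gene_id[i], n_cancer = length(ca), n_normal = length(no),
      cancer_median = median(ca),
      fold_change = as.numeric(median_fold_change(ca, no)),
      percentile_ratio = as.numeric(percentile_ratio_distance(ca, no)),
      overlap_score = overlap_score(ca, no),
      p_value = mann_whitney_p(ca, no),
      stats_defined = TRUE
    )
  })
  if (!is.null(blood_p95)) {
    blood_p95 <- as_tibble(blood_p95)
    if (!"gene" %in% names(blood_p95)) {
      abort_validation("blood_p95 must carry a 'gene' column (see summarize_blood())")
    }
    recs <- left_join(recs, blood_p95, by = "gene")
  }
  new_gene_screen(recs, criteria)
}

new_gene_screen <- function(data, criteria = screen_criteria()) {
  structure(as_tibble(data),
            criteria = criteria,
            class = c("gene_screen", class(as_tibble(data))))
}

blood_columns <- function(records) {
  grep("^blood_p95_", names(records), value = TRUE)
}

blood_threshold_for <- function(criteria, source) {
  bt <- criteria$blood_p95_max
  if (is.null(names(bt)) || !any(nzchar(names(bt)))) return(unname(bt[1]))
  if (source %in% names(bt)) return(unname(bt[[source]]))
  # unknown source falls back to the strictest configured bound
  min(bt)
}

#' Partition screen records into strict panel and relaxed remainder
#'
#' Applies the hard criteria of a [screen_criteria()] cascade to each
#' record: every blood 95th percentile at or below its source bound,
#' fold change above `fold_min`, percentile ratio above
#' `percentile_ratio_min`, and tumor median above `cancer_median_min`
#' (plus the overlap bound when promoted to hard). An `NA` statistic
#' fails its criterion — an undefined separation is not a favorable one.
#' Records failing nothing form the strict panel; the rest form the
#' relaxed remainder, each annotated with the list of criteria it
#' failed. Both parts are ordered by descending tumor median with
#' alphabetical symbol as tie-break.
#'
#' @param records A `gene_screen` tibble (or any tibble with the
#'   statistic columns).
#' @param criteria A [screen_criteria()] object; defaults to the one
#'   attached to `records`, else the package defaults.
#' @return A list of class `screen_panel` with tibble elements `strict`
#'   and `relaxed` (the `relaxed` part carries non-empty
#'   `failed_criteria`); `tidy()` flattens it, `glance()` summarizes it.
#' @export
apply_strict_criteria <- function(records, criteria = NULL) {
  criteria <- criteria %||% attr(records, "criteria") %||% screen_criteria()
  records <- as_tibble(records)
  needed <- c("gene", "cancer_median", "fold_change", "percentile_ratio")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort_validation(sprintf("records are missing columns: %s", oxford(missing)))
  }
  bcols <- blood_columns(records)
  fails <- purrr::map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    f <- character()
    for (bc in bcols) {
      src <- sub("^blood_p95_", "", bc)
      v <- r[[bc]]
      if (is.na(v) || v > blood_threshold_for(criteria, src)) f <- c(f, paste0("blood_", src))
    }
    if (is.na(r$fold_change) || r$fold_change <= criteria$fold_min) f <- c(f, "fold")
    if (is.na(r$percentile_ratio) || r$percentile_ratio <= criteria$percentile_ratio_min) {
      f <- c(f, "percentile_ratio")
    }
    if (is.na(r$cancer_median) || r$cancer_median <= criteria$cancer_median_min) {
      f <- c(f, "cancer_median")
    }
    if (criteria$overlap_is_hard && "overlap_score" %in% names(r) &&
        (is.na(r$overlap_score) || r$overlap_score >= criteria$overlap_score_max)) {
      f <- c(f, "overlap")
    }
    f
  })
  records$failed_criteria <- fails
  records$strict_pass <- lengths(fails) == 0L
  ord <- order(-records$cancer_median, records$gene)
  records <- records[ord, ]
  structure(
    list(
      strict = filter(records, .data$strict_pass),
      relaxed = filter(records, !.data$strict_pass)
    ),
    criteria = criteria,
    class = "screen_panel"
  )
}

#' @export
print.screen_panel <- function(x, ...) {
  cat(sprintf("<screen_panel> %d strict, %d relaxed\n",
              nrow(x$strict), nrow(x$relaxed)))
  if (nrow(x$strict)) {
    cat("strict panel:", oxford(x$strict$gene, max = 10), "\n")
  }
  invisible(x)
}

#' Write and read the candidate panel report
#'
#' The report is a TSV mirroring the candidate-panel layout: one row per
#' gene with `gene`, `cancer_median_rpkm`, `fold_change`,
#' `percentile_ratio`, `overlap_score`, the `blood_p95_<source>`
#' columns, `p_value`, `strict_pass` and the comma-joined
#' `failed_criteria`. Strict rows come first. Values are written at full
#' double precision so a read-back reproduces the records exactly.
#'
#' @param panel A `screen_panel` (from [apply_strict_criteria()]) or an
#'   annotated records tibble with `strict_pass`/`failed_criteria`.
#' @param path Output TSV path.
#' @return [write_panel_report()] invisibly returns `path`;
#'   [read_panel_report()] returns the records tibble with
#'   `failed_criteria` restored as a list column.
#' @export
write_panel_report <- function(panel, path) {
  records <- if (inherits(panel, "screen_panel")) tidy(panel) else as_tibble(panel)
  if (!"failed_criteria" %in% names(records)) records$failed_criteria <- list(character())
  out <- records %>%
    mutate(failed_criteria = purrr::map_chr(.data$failed_criteria,
                                            ~ paste(.x, collapse = ",")))
  if ("cancer_median" %in% names(out)) {
    out <- rename(out, cancer_median_rpkm = "cancer_median")
  }
  front <- intersect(
    c("gene", "cancer_median_rpkm", "fold_change", "percentile_ratio", "overlap_score"),
    names(out)
  )
  back <- intersect(c("p_value", "strict_pass", "failed_criteria"), names(out))
  blood <- blood_columns(out)
  rest <- setdiff(names(out), c(front, blood, back))
  out <- out[, c(front, blood, back, rest)]
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) abort_io(sprintf("cannot write panel report to %s: %s",
                                         path, conditionMessage(e)))
  )
  invisible(path)
}

#' @rdname write_panel_report
#' @export
read_panel_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("panel report not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("cancer_median_rpkm" %in% names(out)) {
    out <- rename(out, cancer_median = "cancer_median_rpkm")
  }
  if ("failed_criteria" %in% names(out)) {
    out$failed_criteria <- purrr::map(out$failed_criteria, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
    })
  }
  out
}
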