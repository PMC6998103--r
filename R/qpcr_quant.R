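#' Long-format Cq tables
#'
#' RT-qPCR measurements are handled as a long tibble with one row per
#' (sample, gene): columns `sample_id`, `gene`, `cq` (quantification
#' cycle; `NA` means undetected, never imputed) and `group` (`normal`,
#' `cancer` or `metastatic_cancer`). Technical replicates may appear as
#' repeated (sample, gene) rows and are averaged arithmetically on the
#' Cq scale before any other step.
#'
#' @param path Path to a TSV with columns `sample_id`, `gene`, `cq`,
#'   `group`; `NA` encodes undetected reactions.
#' @return A validated Cq tibble.
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Cq table not found: %s", path))
  tb <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      gene = readr::col_character(),
      cq = readr::col_double(),
      group = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (any(tb$cq <= 0, na.rm = TRUE)) {
    abort_validation("Cq values must be positive cycles (NA for undetected)")
  }
  validate_cq_table(tb)
}

validate_cq_table <- function(tb) {
  tb <- as_tibble(tb)
  needed <- c("sample_id", "gene", "cq", "group")
  missing <- setdiff(needed, names(tb))
  if (length(missing)) {
    abort_validation(sprintf("Cq table is missing columns: %s", oxford(missing)))
  }
  bad <- setdiff(unique(tb$group), c("normal", "cancer", "metastatic_cancer"))
  if (length(bad)) {
    abort_validation(sprintf("unknown Cq group(s): %s", oxford(bad)))
  }
  tb[needed]
}

#' Average technical replicates on the Cq scale
#'
#' Repeated (sample, gene) rows are merged to their arithmetic mean Cq
#' over detected replicates; a pair whose replicates are all undetected
#' stays a single `NA` row.
#'
#' @param table A Cq tibble.
#' @return A Cq tibble with unique (sample, gene) rows.
#' @export
average_technical_replicates <- function(table) {
  table <- validate_cq_table(table)
  table %>%
    group_by(.data$sample_id, .data$gene, .data$group) %>%
    summarise(
      cq = if (all(is.na(.data$cq))) NA_real_ else mean(.data$cq, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    select("sample_id", "gene", "cq", "group")
}

#' Detectability filter on mean Cq
#'
#' First-stage gene triage: a gene advances only when its mean Cq over
#' detected samples is below `max_cq` cycles (default 33 — beyond that,
#' amplification is too late to be trusted as real signal). Genes with
#' no detected value at all are excluded.
#'
#' @param table A Cq tibble (first-stage samples).
#' @param max_cq Detectability ceiling in cycles.
#' @return Character vector of genes passing the filter, in order of
#'   first appearance.
#' @export
detectability_filter <- function(table, max_cq = 33) {
  table <- average_technical_replicates(table)
  means <- table %>%
    group_by(.data$gene) %>%
    summarise(
      mean_cq = if (all(is.na(.data$cq))) NA_real_ else mean(.data$cq, na.rm = TRUE),
      .groups = "drop"
    )
  keep <- means$gene[!is.na(means$mean_cq) & means$mean_cq < max_cq]
  intersect(unique(table$gene), keep)
}

#' Reference-gene (delta-Cq) normalization
#'
#' Subtracts, within each sample, the reference gene's Cq from every
#' target gene's Cq: `dCq(sample, gene) = Cq(sample, gene) -
#' Cq(sample, reference)`. The reference row is removed from the
#' output. A sample whose reference reaction is missing cannot be
#' normalized and is dropped with a warning naming it.
#'
#' @param table A Cq tibble with unique (sample, gene) rows (run
#'   [average_technical_replicates()] first if needed).
#' @param reference_gene Reference (housekeeping) gene symbol; default
#'   `"PPIA"`, a stably expressed kidney reference.
#' @return A Cq tibble whose `cq` column now holds delta-Cq values;
#'   attribute `reference_gene` records the reference used.
#' @export
normalize_to_reference <- function(table, reference_gene = "PPIA") {
  table <- validate_cq_table(table)
  if (!reference_gene %in% table$gene) {
    abort_validation(sprintf("reference gene '%s' absent from Cq table", reference_gene))
  }
  ref <- table %>%
    filter(.data$gene == reference_gene) %>%
    select("sample_id", ref_cq = "cq")
  out <- table %>%
    filter(.data$gene != reference_gene) %>%
    left_join(ref, by = "sample_id")
  dropped <- unique(out$sample_id[is.na(out$ref_cq)])
  if (length(dropped)) {
    warning(sprintf("sample(s) without reference '%s' Cq dropped: %s",
                    reference_gene, oxford(dropped)), call. = FALSE)
    out <- filter(out, !is.na(.data$ref_cq))
  }
  out <- out %>%
    mutate(cq = .data$cq - .data$ref_cq) %>%
    select("sample_id", "gene", "cq", "group")
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Relative quantities from (delta-)Cq values
#'
#' For one gene's vector of Cq (or delta-Cq) values across samples,
#' \deqn{RQ_i = 2^{(\bar{Cq} - Cq_i)},} the mean taken over detected
#' samples of that gene: a sample one cycle earlier than the gene's mean
#' has twice the relative quantity. The base of 2 encodes an assumed
#' 100% PCR efficiency. By construction the geometric mean of the
#' detected RQ values is exactly 1. Undetected values stay `NA`.
#'
#' @param values Numeric Cq or delta-Cq values for one gene; at least
#'   one detected value.
#' @return Relative quantities, same length as `values`.
#' @examples
#' relative_quantity(c(27, 28, 29))  # 2, 1, 0.5
#' @export
relative_quantity <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    abort_validation("relative quantities need at least one detected Cq value")
  }
  2^(mean(values, na.rm = TRUE) - values)
}

#' @rdname relative_quantity
#' @param table A Cq tibble; RQ is computed per gene across its
#'   samples and added as column `rq`.
#' @export
add_relative_quantity <- function(table) {
  table <- validate_cq_table(table)
  table %>%
    group_by(.data$gene) %>%
    mutate(rq = if (all(is.na(.data$cq))) NA_real_ else relative_quantity(.data$cq)) %>%
    ungroup()
}

#' Signed group fold change from Cq means
#'
#' The raw fold change between two groups is `2^(mean Cq baseline -
#' mean Cq case)` (lower Cq in the case group means more transcript).
#' Fold changes are reported with the usual signed convention: the raw
#' ratio when at least 1, and the negative reciprocal (`-1/raw`) when
#' below 1, so magnitude is always at least 1 and sign encodes
#' direction (negative = down in the case group).
#'
#' @param baseline,case Numeric Cq (or delta-Cq) vectors of detected
#'   values for the two groups; undetected values are ignored.
#' @return A single signed fold change.
#' @examples
#' group_fold_change(rep(30, 3), rep(25, 3))  # +32
#' group_fold_change(rep(25, 3), rep(30, 3))  # -32
#' @export
group_fold_change <- function(baseline, case) {
  baseline <- baseline[!is.na(baseline)]
  case <- case[!is.na(case)]
  if (!length(baseline) || !length(case)) {
    abort_validation("fold change needs at least one detected Cq in each group")
  }
  signed_fold(2^(mean(baseline) - mean(case)))
}

signed_fold <- function(raw) {
  if (is.na(raw)) return(NA_real_)
  if (raw >= 1) raw else -1 / raw
}

#' Significance verdict from fold change and p-value
#'
#' Vectorized verdict rule shared by [compare_groups()] and
#' fixture-based reproduction: `"up"` when `p < alpha` and the signed
#' fold is positive, `"down"` when `p < alpha` and the signed fold is
#' negative, `"ns"` otherwise.
#'
#' @param fold_change_signed Signed fold changes (magnitude >= 1).
#' @param p_value Two-sided p-values.
#' @param alpha Significance level.
#' @return Character vector of verdicts.
#' @export
qpcr_verdict <- function(fold_change_signed, p_value, alpha = 0.05) {
  dplyr::case_when(
    is.na(p_value) | is.na(fold_change_signed) ~ "ns",
    p_value < alpha & fold_change_signed > 0 ~ "up",
    p_value < alpha & fold_change_signed < 0 ~ "down",
    TRUE ~ "ns"
  )
}

resolve_comparison <- function(comparison) {
  switch(comparison,
    normal_vs_cancer = list(baseline = "normal",
                            case = c("cancer", "metastatic_cancer")),
    nonmetastatic_vs_metastatic = list(baseline = "cancer",
                                       case = "metastatic_cancer"),
    abort_validation(sprintf("unknown comparison '%s'", comparison))
  )
}

#' Per-gene group comparison of relative quantities
#'
#' For each gene, compares relative quantities between two groups with a
#' two-sided Mann-Whitney U test and reports the signed fold change
#' computed from the group mean (delta-)Cq values. Two groupings mirror
#' the usual blood-testing designs: `"normal_vs_cancer"` pools
#' non-metastatic and metastatic cancer into one case group against
#' normal/healthy samples, and `"nonmetastatic_vs_metastatic"` compares
#' the two cancer strata.
#'
#' Genes with fewer than two detected samples in a group are flagged
#' `underpowered` (their p-value is still computed when defined); a
#' detection rate below 50% in either group sets `low_detection`.
#'
#' @param table A Cq tibble with unique (sample, gene) rows, typically
#'   reference-normalized ([normalize_to_reference()]); an `rq` column
#'   is added via [add_relative_quantity()] when absent.
#' @param comparison `"normal_vs_cancer"` or
#'   `"nonmetastatic_vs_metastatic"`.
#' @param alpha Significance level for verdicts.
#' @return A tibble of class `qpcr_comparison`: one row per gene with
#'   group sizes, detection rates, `fold_change_signed`, `p_value`,
#'   `verdict` and flags.
#' @export
compare_groups <- function(table, comparison = "normal_vs_cancer", alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must lie in (0, 1)")
  table <- add_relative_quantity(validate_cq_table(table))
  grp <- resolve_comparison(comparison)
  table <- table %>%
    mutate(side = dplyr::case_when(
      .data$group %in% grp$baseline ~ "baseline",
      .data$group %in% grp$case ~ "case",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$side))
  if (!nrow(table)) abort_validation("no samples fall into the requested comparison groups")
  res <- table %>%
    group_by(.data$gene) %>%
    group_split() %>%
    purrr::map_dfr(function(g) {
      b <- g[g$side == "baseline", ]
      ca <- g[g$side == "case", ]
      det_b <- b$cq[!is.na(b$cq)]
      det_c <- ca$cq[!is.na(ca$cq)]
      fold <- if (length(det_b) && length(det_c)) group_fold_change(b$cq, ca$cq) else NA_real_
      rq_b <- b$rq[!is.na(b$rq)]
      rq_c <- ca$rq[!is.na(ca$rq)]
      p <- if (length(rq_b) && length(rq_c)) mann_whitney_p(rq_b, rq_c) else NA_real_
      tibble(
        gene = g$gene[1],
        n_baseline = nrow(b), n_case = nrow(ca),
        detected_baseline = length(det_b), detected_case = length(det_c),
        fold_change_signed = fold,
        p_value = p,
        verdict = qpcr_verdict(fold, p, alpha),
        underpowered = length(det_b) < 2L || length(det_c) < 2L,
        low_detection = (nrow(b) > 0L && length(det_b) / nrow(b) < 0.5) ||
          (nrow(ca) > 0L && length(det_c) / nrow(ca) < 0.5)
      )
    })
  res <- res[match(unique(table$gene), res$gene), ]
  structure(res, alpha = alpha, comparison = comparison,
            class = c("qpcr_comparison", class(res)))
}
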