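#' Bundled ccRCC screening fixtures
#'
#' Three small curated tables derived from public ccRCC tumor/normal and
#' healthy-blood expression resources ship with the package so that the
#' screening cascade and the qPCR verdict logic can be exercised without
#' any download:
#'
#' \describe{
#'   \item{`ccrcc_candidate_panel()`}{31 candidate genes with their
#'     screening statistics: tumor median (rpkm), median fold change,
#'     percentile-ratio distance and blood 95th percentiles for a pooled
#'     GEO-style group and a GTEx-style group. The published layout runs
#'     numeric columns together in places; this encoding follows the
#'     values anchored in the accompanying text, and one row (FBXO17)
#'     whose digits cannot be segmented unambiguously carries
#'     `note = "ambiguous"`.}
#'   \item{`ccrcc_detectability()`}{22 candidate genes with the
#'     tissue-level qPCR confirmation status and the mean Cq observed in
#'     a first-stage blood test; genes whose amplification stayed above
#'     the 33-cycle ceiling have `cq_status = "above_ceiling"` and a
#'     missing `mean_cq` (right-censored measurements are encoded as
#'     undetected).}
#'   \item{`ccrcc_qpcr_results()`}{Second-stage blood results for the 9
#'     detectable genes: signed fold change (cancer vs normal blood),
#'     Mann-Whitney p-value and the published verdict.}
#' }
#'
#' @return A tibble (see individual descriptions).
#' @name ccrcc_fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "rccpanel")
  if (!nzchar(p)) abort_io(sprintf("bundled fixture not found: %s", file))
  p
}

#' @rdname ccrcc_fixtures
#' @export
ccrcc_candidate_panel <- function() {
  readr::read_tsv(
    fixture_path("candidate_panel.tsv"),
    col_types = readr::cols(
      gene = readr::col_character(),
      note = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  ) %>%
    rename(cancer_median = "cancer_median_rpkm")
}

#' @rdname ccrcc_fixtures
#' @export
ccrcc_detectability <- function() {
  readr::read_tsv(
    fixture_path("blood_detectability.tsv"),
    col_types = readr::cols(
      gene = readr::col_character(),
      tissue_confirmed = readr::col_character(),
      tissue_fold_change = readr::col_double(),
      mean_cq = readr::col_double(),
      cq_status = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
}

#' @rdname ccrcc_fixtures
#' @export
ccrcc_qpcr_results <- function() {
  readr::read_tsv(
    fixture_path("blood_qpcr_results.tsv"),
    col_types = readr::cols(
      gene = readr::col_character(),
      fold_change_signed = readr::col_double(),
      p_value = readr::col_double(),
      verdict = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
}

#' First-stage detectability fixture as a Cq table
#'
#' Recasts [ccrcc_detectability()] into the long Cq format consumed by
#' [detectability_filter()]: one pseudo-sample per gene holding the
#' stage-one mean Cq, with above-ceiling genes encoded as undetected.
#'
#' @return A Cq tibble with one row per fixture gene.
#' @export
ccrcc_detectability_cq <- function() {
  fx <- ccrcc_detectability()
  tibble(
    sample_id = "stage1_mean",
    gene = fx$gene,
    cq = fx$mean_cq,
    group = "cancer"
  )
}
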