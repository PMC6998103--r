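#' Ground-truth table for synthetic cohorts
#'
#' Each simulated gene is described by the generating parameters the
#' recovery tests need to check against: a baseline log2 expression, a
#' tumor log2 shift (0 for null genes), a blood log2 level (`NA` marks a
#' blood-absent gene), a log2-scale dispersion and a qPCR group shift in
#' cycles. Planted candidate genes are "tumor-up, blood-absent": large
#' positive tumor shift, `NA` blood level.
#'
#' Defaults emulate the statistical structure of a bulk tumor/normal
#' RNA-seq cohort: log-normal per-gene expression around a median of a
#' few rpkm, unit log2 dispersion, planted candidates shifted 4 log2
#' units (16-fold), and null genes expressed in blood around 2 rpkm.
#'
#' @param n_genes Total number of genes.
#' @param n_planted Number of planted candidate genes (placed first).
#' @param base_log2 Baseline log2 rpkm for every gene.
#' @param planted_shift Tumor log2 shift of planted genes.
#' @param blood_level_log2 Blood log2 rpkm of non-planted genes.
#' @param dispersion Log2-scale standard deviation (> 0).
#' @param planted_cq_shift qPCR group shift, in cycles, of planted
#'   genes (positive = lower Cq, i.e. up in cancer blood).
#' @return A tibble of class `synthetic_truth`, one row per gene.
#' @export
simulate_truth <- function(n_genes, n_planted = 0L, base_log2 = 3,
                           planted_shift = 4, blood_level_log2 = 1,
                           dispersion = 1, planted_cq_shift = 0) {
  if (n_genes < 1L) abort_validation("n_genes must be >= 1")
  if (n_planted < 0L || n_planted > n_genes) {
    abort_validation("n_planted must lie in [0, n_genes]")
  }
  if (dispersion <= 0) abort_validation("dispersion must be > 0")
  planted <- seq_len(n_genes) <= n_planted
  out <- tibble(
    gene = sprintf("G%04d", seq_len(n_genes)),
    planted = planted,
    base_log2 = base_log2,
    tumor_log2_shift = if_else(planted, planted_shift, 0),
    blood_log2_level = if_else(planted, NA_real_, blood_level_log2),
    dispersion = dispersion,
    qpcr_group_shift_cycles = if_else(planted, planted_cq_shift, 0)
  )
  structure(out, class = c("synthetic_truth", class(out)))
}

validate_truth <- function(truth) {
  truth <- as_tibble(truth)
  needed <- c("gene", "base_log2", "tumor_log2_shift", "blood_log2_level",
              "dispersion", "qpcr_group_shift_cycles")
  missing <- setdiff(needed, names(truth))
  if (length(missing)) {
    abort_validation(sprintf("truth table is missing columns: %s", oxford(missing)))
  }
  if (any(truth$dispersion <= 0)) abort_validation("dispersion must be > 0 for all genes")
  if (anyDuplicated(truth$gene)) abort_validation("truth table has duplicate genes")
  truth
}

# One log-normal expression matrix: log2 value ~ Normal(mu, sd) per gene.
lognormal_matrix <- function(mu, sd, n_samples, sample_prefix) {
  vals <- t(vapply(seq_along(mu), function(i) {
    2^rnorm(n_samples, mean = mu[i], sd = sd[i])
  }, numeric(n_samples)))
  if (n_samples == 1L) vals <- matrix(vals, ncol = 1L)
  colnames(vals) <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
  vals
}

#' Simulate a tumor / matched-normal expression cohort
#'
#' Draws per-gene rpkm values log-normally: `log2(value) ~
#' Normal(base_log2 + tumor_log2_shift * [cancer], dispersion)`. The
#' default cohort sizes (470 tumor, 68 matched normal) mirror a large
#' public ccRCC cohort with a matched-normal subset. Deterministic given
#' `seed` (Mersenne-Twister via [set.seed()]).
#'
#' @param truth A [simulate_truth()] table.
#' @param n_cancer,n_normal Cohort sizes.
#' @param seed Integer seed.
#' @return A list with `tumor` and `normal` [expr_matrix()] objects (in
#'   rpkm) and the `truth` table.
#' @export
simulate_tissue_cohort <- function(truth, n_cancer = 470L, n_normal = 68L,
                                   seed = 1L) {
  truth <- validate_truth(truth)
  if (n_cancer < 1L || n_normal < 1L) {
    abort_validation("cohort sizes must be >= 1")
  }
  set.seed(seed)
  tum <- lognormal_matrix(truth$base_log2 + truth$tumor_log2_shift,
                          truth$dispersion, n_cancer, "T")
  nor <- lognormal_matrix(truth$base_log2, truth$dispersion, n_normal, "N")
  list(
    tumor = expr_matrix(tibble(gene_id = truth$gene, as_tibble(tum)), unit = "rpkm"),
    normal = expr_matrix(tibble(gene_id = truth$gene, as_tibble(nor)), unit = "rpkm"),
    truth = truth
  )
}

#' Simulate healthy-blood baseline sources
#'
#' Generates one rpkm matrix per blood source. Blood-present genes
#' (finite `blood_log2_level`) are drawn log-normally around their
#' level. Blood-absent genes (`NA` level) yield a point mass at zero
#' with a small contamination rate of spurious low-level signal
#' (uniform on (0, 0.1] rpkm), so that absence filters are exercised on
#' near-zero — not exactly zero — data. The default source layout
#' mirrors a pooled compendium of small public whole-blood datasets
#' (75 samples) next to one large population resource (376 samples).
#'
#' @param truth A [simulate_truth()] table.
#' @param n_samples Named integer vector: samples per source.
#' @param blood_dispersion Log2 dispersion of blood-present genes.
#' @param contamination Per-sample probability of spurious signal in a
#'   blood-absent gene.
#' @param seed Integer seed.
#' @return Named list of [expr_matrix()] objects, one per source.
#' @export
simulate_blood_sources <- function(truth,
                                   n_samples = c(geo = 75L, gtex = 376L),
                                   blood_dispersion = 0.5,
                                   contamination = 0.01,
                                   seed = 1L) {
  truth <- validate_truth(truth)
  if (!length(n_samples) || is.null(names(n_samples))) {
    abort_validation("n_samples must be a named vector of source sizes")
  }
  set.seed(seed)
  out <- lapply(names(n_samples), function(lab) {
    ns <- n_samples[[lab]]
    vals <- t(vapply(seq_len(nrow(truth)), function(i) {
      lev <- truth$blood_log2_level[i]
      if (is.na(lev)) {
        hit <- runif(ns) < contamination
        v <- numeric(ns)
        v[hit] <- runif(sum(hit), 0, 0.1)
        v
      } else {
        2^rnorm(ns, mean = lev, sd = blood_dispersion)
      }
    }, numeric(ns)))
    if (ns == 1L) vals <- matrix(vals, ncol = 1L)
    colnames(vals) <- sprintf("%s_%03d", lab, seq_len(ns))
    expr_matrix(tibble(gene_id = truth$gene, as_tibble(vals)), unit = "rpkm")
  })
  setNames(out, names(n_samples))
}

#' Simulate an RT-qPCR blood experiment
#'
#' Generates a long Cq table with planted group effects: `Cq =
#' base_cycles - qpcr_group_shift_cycles * [cancer] + Normal(0, sd)`,
#' so a positive shift lowers cancer Cq (upregulation in cancer blood)
#' and a shift of -1.07 cycles corresponds to a signed fold change near
#' -2.1. Metastatic samples receive the same cancer shift plus an
#' optional extra metastatic shift. The reference gene is generated
#' with zero shift in every group. Default group sizes (11 normal, 10
#' non-metastatic, 6 metastatic) mirror a small patient blood cohort.
#'
#' @param truth A [simulate_truth()] table.
#' @param n_normal,n_cancer,n_metastatic Group sizes.
#' @param base_cycles Baseline Cq of every gene.
#' @param sd Cycle-scale measurement noise.
#' @param metastatic_extra_shift Additional cycles subtracted for
#'   metastatic samples.
#' @param reference_gene Name of the generated reference gene.
#' @param seed Integer seed.
#' @return A Cq tibble (see [read_cq_table()]).
#' @export
simulate_cq_experiment <- function(truth, n_normal = 11L, n_cancer = 10L,
                                   n_metastatic = 6L, base_cycles = 28,
                                   sd = 0.5, metastatic_extra_shift = 0,
                                   reference_gene = "PPIA", seed = 1L) {
  truth <- validate_truth(truth)
  if (n_normal < 0L || n_cancer < 0L || n_metastatic < 0L) {
    abort_validation("group sizes must be >= 0")
  }
  if (reference_gene %in% truth$gene) {
    abort_validation(sprintf("reference gene '%s' collides with a truth gene", reference_gene))
  }
  set.seed(seed)
  samples <- tibble(
    sample_id = c(sprintf("Bn%02d", seq_len(n_normal)),
                  sprintf("Bc%02d", seq_len(n_cancer)),
                  sprintf("Bm%02d", seq_len(n_metastatic))),
    group = rep(c("normal", "cancer", "metastatic_cancer"),
                times = c(n_normal, n_cancer, n_metastatic))
  )
  genes <- tibble(
    gene = c(truth$gene, reference_gene),
    shift = c(truth$qpcr_group_shift_cycles, 0)
  )
  grid <- tidyr::crossing(samples, genes)
  grid %>%
    mutate(
      effect = dplyr::case_when(
        .data$group == "normal" ~ 0,
        .data$group == "cancer" ~ .data$shift,
        .data$group == "metastatic_cancer" ~ .data$shift +
          if_else(.data$gene == reference_gene, 0, metastatic_extra_shift)
      ),
      cq = base_cycles - .data$effect + rnorm(dplyr::n(), 0, sd)
    ) %>%
    select("sample_id", "gene", "cq", "group")
}
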