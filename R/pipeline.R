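#' Read a pipeline configuration file
#'
#' Configurations are plain named lists; on disk they are YAML (`.yml`,
#' `.yaml`) or JSON (`.json`). Every `run_*()` driver accepts either
#' the list or a file path. Unknown fields are an error, so typos in a
#' config fail loudly rather than silently falling back to defaults.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort_validation(sprintf("unsupported config extension '.%s' (use yaml or json)", ext))
  )
  if (!is.list(cfg)) abort_validation("config must be a mapping of fields to values")
  cfg
}

resolve_config <- function(config, defaults, context) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  if (!is.list(config)) abort_validation(sprintf("%s config must be a list or a file path", context))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort_validation(sprintf("unknown %s config field(s): %s", context, oxford(unknown)))
  }
  modifyList(defaults, config)
}

require_path <- function(path, what) {
  if (is.null(path)) abort_validation(sprintf("config is missing the %s path", what))
  if (!file.exists(path)) abort_io(sprintf("%s path does not exist: %s", what, path))
  path
}

ensure_out_dir <- function(out_dir) {
  if (is.null(out_dir)) abort_validation("config is missing out_dir")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_io(sprintf("cannot create output directory: %s", out_dir))
  out_dir
}

write_run_log <- function(log, out_dir, name) {
  path <- file.path(out_dir, name)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Generate a synthetic dataset directory
#'
#' Runs the three generators under one seed and writes a self-contained
#' dataset: `tumor.tsv` and `normal.tsv` (rpkm matrices),
#' `blood_<source>.tsv` per blood source, `cq.tsv` (long Cq table) and
#' `truth.json` (the generating parameters). Reruns with the same
#' config are byte-identical.
#'
#' Config fields (defaults in parentheses): `out_dir`, `seed` (1),
#' `n_genes` (500), `n_planted` (10), `n_cancer` (470), `n_normal`
#' (68), `blood_samples` (geo = 75, gtex = 376), `cq_normal` (11),
#' `cq_cancer` (10), `cq_metastatic` (6), `planted_shift` (4),
#' `planted_cq_shift` (0), `dispersion` (1), `blood_level_log2` (1),
#' `base_log2` (3).
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Invisibly, a list with the written `paths` and the `truth`
#'   table.
#' @export
run_simulate <- function(config = list()) {
  defaults <- list(
    out_dir = NULL, seed = 1L, n_genes = 500L, n_planted = 10L,
    n_cancer = 470L, n_normal = 68L,
    blood_samples = c(geo = 75L, gtex = 376L),
    cq_normal = 11L, cq_cancer = 10L, cq_metastatic = 6L,
    planted_shift = 4, planted_cq_shift = 0, dispersion = 1,
    blood_level_log2 = 1, base_log2 = 3
  )
  cfg <- resolve_config(config, defaults, "simulate")
  out_dir <- ensure_out_dir(cfg$out_dir)
  truth <- simulate_truth(
    n_genes = cfg$n_genes, n_planted = cfg$n_planted,
    base_log2 = cfg$base_log2, planted_shift = cfg$planted_shift,
    blood_level_log2 = cfg$blood_level_log2, dispersion = cfg$dispersion,
    planted_cq_shift = cfg$planted_cq_shift
  )
  seed <- as.integer(cfg$seed)
  cohort <- simulate_tissue_cohort(truth, n_cancer = cfg$n_cancer,
                                   n_normal = cfg$n_normal, seed = seed)
  blood_sizes <- unlist(cfg$blood_samples)
  blood <- simulate_blood_sources(truth, n_samples = blood_sizes, seed = seed + 1L)
  cq <- simulate_cq_experiment(truth, n_normal = cfg$cq_normal,
                               n_cancer = cfg$cq_cancer,
                               n_metastatic = cfg$cq_metastatic, seed = seed + 2L)
  paths <- c(
    tumor = file.path(out_dir, "tumor.tsv"),
    normal = file.path(out_dir, "normal.tsv")
  )
  write_expression_matrix(cohort$tumor, paths[["tumor"]])
  write_expression_matrix(cohort$normal, paths[["normal"]])
  for (lab in names(blood)) {
    p <- file.path(out_dir, sprintf("blood_%s.tsv", lab))
    write_expression_matrix(blood[[lab]], p)
    paths[[paste0("blood_", lab)]] <- p
  }
  paths[["cq"]] <- file.path(out_dir, "cq.tsv")
  readr::write_tsv(cq, paths[["cq"]], progress = FALSE)
  paths[["truth"]] <- file.path(out_dir, "truth.json")
  jsonlite::write_json(as.data.frame(truth), paths[["truth"]],
                       pretty = TRUE, digits = NA)
  message(sprintf("simulated %d genes (%d planted); %d+%d tissue samples, %s blood samples, %d Cq samples",
                  cfg$n_genes, cfg$n_planted, cfg$n_cancer, cfg$n_normal,
                  paste(blood_sizes, collapse = "+"),
                  cfg$cq_normal + cfg$cq_cancer + cfg$cq_metastatic))
  invisible(list(paths = paths, truth = truth))
}

#' Run the candidate screen end to end
#'
#' Loads the tumor and normal matrices (plus optional blood sources),
#' applies the preparation steps in order — alias collapse, per-subject
#' averaging, rpkm normalization when counts are supplied — then
#' computes per-gene screening statistics, partitions them with the
#' strict criteria and writes `panel_report.tsv` together with a
#' machine-readable `screen_log.json` of stage-by-stage gene and sample
#' counts. Identical configs yield byte-identical outputs.
#'
#' Config fields: `tumor`, `normal` (matrix TSV paths, required),
#' `unit` ("rpkm" or "counts"), `annotation` (gene lengths TSV,
#' required for counts), `rpkm_mode` ("standard"), `alias_map` (TSV
#' with columns alias, gene_id), `tumor_meta`/`normal_meta` (metadata
#' TSVs enabling per-subject averaging), `blood` (named vector of rpkm
#' matrix paths), `blood_groups` (named list pooling sources),
#' `criteria` (named list of [screen_criteria()] overrides) and
#' `out_dir` (required).
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Invisibly, a list with the `panel` (a `screen_panel`), the
#'   `records` tibble and the written `paths`.
#' @export
run_screen <- function(config) {
  defaults <- list(
    tumor = NULL, normal = NULL, unit = "rpkm", annotation = NULL,
    rpkm_mode = "standard", alias_map = NULL, tumor_meta = NULL,
    normal_meta = NULL, blood = NULL, blood_groups = NULL,
    criteria = list(), out_dir = NULL
  )
  cfg <- resolve_config(config, defaults, "screen")
  out_dir <- ensure_out_dir(cfg$out_dir)
  log <- list(stages = list())
  note_stage <- function(stage, ...) {
    log$stages[[length(log$stages) + 1L]] <<- c(list(stage = stage), list(...))
  }

  load_side <- function(which) {
    m <- read_expression_matrix(require_path(cfg[[which]], which), unit = cfg$unit)
    note_stage(paste0("load_", which), genes = nrow(m), samples = length(sample_ids(m)))
    if (!is.null(cfg$alias_map)) {
      amap <- readr::read_tsv(require_path(cfg$alias_map, "alias_map"),
                              col_types = readr::cols(.default = readr::col_character()),
                              progress = FALSE, show_col_types = FALSE)
      m <- collapse_max(m, amap)
      note_stage(paste0("collapse_", which), genes = nrow(m))
    } else if (anyDuplicated(m$gene_id)) {
      m <- collapse_max(m)
      note_stage(paste0("collapse_", which), genes = nrow(m))
    }
    meta_field <- paste0(which, "_meta")
    if (!is.null(cfg[[meta_field]])) {
      meta <- read_sample_metadata(require_path(cfg[[meta_field]], meta_field))
      m <- average_per_subject(m, meta)
      note_stage(paste0("average_", which), samples = length(sample_ids(m)))
    }
    if (cfg$unit == "counts") {
      ann <- readr::read_tsv(require_path(cfg$annotation, "annotation"),
                             col_types = readr::cols(gene_id = readr::col_character(),
                                                     length = readr::col_double()),
                             progress = FALSE, show_col_types = FALSE)
      m <- compute_rpkm(m, ann, mode = cfg$rpkm_mode)
      note_stage(paste0("rpkm_", which), genes = nrow(m))
    }
    m
  }

  tumor <- load_side("tumor")
  normal <- load_side("normal")

  crit_args <- cfg$criteria
  if (!is.null(crit_args$blood_p95_max)) crit_args$blood_p95_max <- unlist(crit_args$blood_p95_max)
  criteria <- do.call(screen_criteria, crit_args)

  blood_p95 <- NULL
  if (!is.null(cfg$blood)) {
    sources <- lapply(cfg$blood, function(p) {
      read_expression_matrix(require_path(p, "blood source"), unit = "rpkm")
    })
    names(sources) <- names(cfg$blood)
    blood_p95 <- summarize_blood(sources, groups = cfg$blood_groups,
                                 genes = tumor$gene_id)
    note_stage("summarize_blood", sources = length(sources),
               groups = length(blood_columns(blood_p95)))
  }

  records <- screen_genes(tumor, normal, blood_p95 = blood_p95, criteria = criteria)
  note_stage("screen_genes", genes = nrow(records))
  panel <- apply_strict_criteria(records, criteria)
  note_stage("apply_strict_criteria", strict = nrow(panel$strict),
             relaxed = nrow(panel$relaxed))

  paths <- c(report = file.path(out_dir, "panel_report.tsv"))
  write_panel_report(panel, paths[["report"]])
  paths[["log"]] <- write_run_log(log, out_dir, "screen_log.json")
  invisible(list(panel = panel, records = records, paths = paths))
}

#' Run the RT-qPCR analysis stage
#'
#' Loads a long-format Cq table and runs the quantification cascade:
#' technical-replicate averaging, detectability filtering (mean Cq below
#' the ceiling), reference-gene delta-Cq normalization (skippable with
#' `use_reference = FALSE`, which reproduces the raw-Cq variant of the
#' relative-quantity formula), per-gene relative quantities, and one
#' group comparison per configured grouping. Per grouping a results TSV
#' (`qpcr_<comparison>.tsv`) is written, plus a per-sample `rq.tsv` for
#' plotting and a `qpcr_log.json` with stage-by-stage counts.
#'
#' Config fields: `cq` (Cq table TSV, required), `reference_gene`
#' ("PPIA"), `use_reference` (TRUE), `max_cq` (33), `apply_detectability`
#' (TRUE), `alpha` (0.05), `comparisons`
#' (c("normal_vs_cancer", "nonmetastatic_vs_metastatic")), `out_dir`
#' (required).
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Invisibly, a list with one `qpcr_comparison` tibble per
#'   grouping, the per-sample `rq` table and the written `paths`.
#' @export
run_qpcr <- function(config) {
  defaults <- list(
    cq = NULL, reference_gene = "PPIA", use_reference = TRUE, max_cq = 33,
    apply_detectability = TRUE, alpha = 0.05,
    comparisons = c("normal_vs_cancer", "nonmetastatic_vs_metastatic"),
    out_dir = NULL
  )
  cfg <- resolve_config(config, defaults, "qpcr")
  out_dir <- ensure_out_dir(cfg$out_dir)
  table <- read_cq_table(require_path(cfg$cq, "cq"))
  if (!nrow(table)) abort_validation(sprintf("Cq table is empty: %s", cfg$cq))
  log <- list(stages = list())
  note_stage <- function(stage, ...) {
    log$stages[[length(log$stages) + 1L]] <<- c(list(stage = stage), list(...))
  }
  table <- average_technical_replicates(table)
  note_stage("load", genes = dplyr::n_distinct(table$gene),
             samples = dplyr::n_distinct(table$sample_id))
  if (isTRUE(cfg$apply_detectability)) {
    keep <- detectability_filter(table, max_cq = cfg$max_cq)
    keep <- union(keep, cfg$reference_gene)
    table <- filter(table, .data$gene %in% keep)
    note_stage("detectability", genes = dplyr::n_distinct(table$gene))
  }
  if (isTRUE(cfg$use_reference)) {
    table <- normalize_to_reference(table, reference_gene = cfg$reference_gene)
    note_stage("normalize", genes = dplyr::n_distinct(table$gene),
               samples = dplyr::n_distinct(table$sample_id))
  }
  rq_table <- add_relative_quantity(table)
  paths <- c(rq = file.path(out_dir, "rq.tsv"))
  readr::write_tsv(rq_table, paths[["rq"]], progress = FALSE)
  results <- list()
  for (cmp in cfg$comparisons) {
    res <- compare_groups(rq_table, comparison = cmp, alpha = cfg$alpha)
    results[[cmp]] <- res
    p <- file.path(out_dir, sprintf("qpcr_%s.tsv", cmp))
    readr::write_tsv(as_tibble(res), p, progress = FALSE)
    paths[[paste0("qpcr_", cmp)]] <- p
    note_stage(paste0("compare_", cmp), genes = nrow(res),
               significant = sum(res$verdict != "ns"))
  }
  paths[["log"]] <- write_run_log(log, out_dir, "qpcr_log.json")
  invisible(list(results = results, rq = rq_table, paths = paths))
}
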