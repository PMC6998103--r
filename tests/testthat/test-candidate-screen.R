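test_that("tissue-specific subtraction removes excluded tissues' genes", {
  sets <- list(kidney = c("A", "B", "C"), blood = "B", bladder = "C",
               liver = character(), prostate = character())
  expect_warning(
    got <- kidney_specific_genes(sets, "kidney",
                                 c("blood", "liver", "prostate", "bladder", "lung")),
    "lung"
  )
  expect_identical(got, "A")
  expect_identical(
    kidney_specific_genes(list(kidney = character(), blood = "B"), "kidney", "blood"),
    character()
  )
  expect_error(kidney_specific_genes(sets, "brain"), class = "rccpanel_validation_error")
})

test_that("tissue-specific subtraction matches per-element membership filtering", {
  set.seed(51)
  universe <- sprintf("SYM%02d", 1:50)
  sets <- list(
    kidney = sample(universe, 30),
    blood = sample(universe, 10),
    liver = sample(universe, 8),
    bladder = sample(universe, 12)
  )
  got <- kidney_specific_genes(sets, "kidney", c("blood", "liver", "bladder"))
  expected <- sort(Filter(
    function(g) !(g %in% sets$blood || g %in% sets$liver || g %in% sets$bladder),
    sets$kidney
  ))
  expect_identical(got, expected)
})

test_that("blood summaries take the 95th percentile over pooled samples", {
  const <- make_expr(matrix(0.5, nrow = 1, ncol = 20), gene_ids = "G")
  got <- summarize_blood(list(src = const))
  expect_equal(got$blood_p95_src, 0.5)

  # pooling two GEO-style datasets equals the oracle on the concatenation
  set.seed(52)
  d1 <- matrix(rlnorm(30), nrow = 2)
  d2 <- matrix(rlnorm(16), nrow = 2)
  colnames(d1) <- sprintf("a%d", 1:15); colnames(d2) <- sprintf("b%d", 1:8)
  src <- list(geo1 = make_expr(d1, gene_ids = c("G1", "G2")),
              geo2 = make_expr(d2, gene_ids = c("G1", "G2")))
  got <- summarize_blood(src, groups = list(geo = c("geo1", "geo2")))
  expect_equal(got$blood_p95_geo,
               c(oracle_percentile(c(d1[1, ], d2[1, ]), 95),
                 oracle_percentile(c(d2[2, ], d1[2, ]), 95)))

  # a gene absent from one source contributes zeros, with a warning
  expect_warning(
    miss <- summarize_blood(
      list(geo1 = src$geo1,
           geo2 = make_expr(d2[1, , drop = FALSE], gene_ids = "G1")),
      groups = list(geo = c("geo1", "geo2"))
    ),
    "G2"
  )
  expect_equal(miss$blood_p95_geo[miss$gene == "G2"],
               oracle_percentile(c(d1[2, ], rep(0, 8)), 95))

  counts <- make_expr(matrix(1, 1, 2), gene_ids = "G", unit = "counts")
  expect_error(summarize_blood(list(x = counts)), class = "rccpanel_validation_error")
})

test_that("screen_genes computes per-gene statistics and flags degenerate genes", {
  set.seed(53)
  truth <- simulate_truth(3, n_planted = 1, planted_shift = 5)
  co <- simulate_tissue_cohort(truth, n_cancer = 40, n_normal = 20, seed = 53)
  rec <- screen_genes(co$tumor, co$normal)
  expect_identical(rec$gene[which.max(rec$fold_change)], truth$gene[truth$planted])

  # identical matrices: unit fold change and no separation anywhere
  same <- screen_genes(co$tumor, co$tumor)
  expect_true(all(same$fold_change == 1))
  expect_true(all(same$p_value >= 0.99))
  expect_true(all(same$overlap_score == 1))

  # a single-sample group leaves statistics undefined
  one <- make_expr(matrix(1:2, ncol = 1), gene_ids = c("A", "B"))
  many <- make_expr(matrix(1:6, nrow = 2), gene_ids = c("A", "B"))
  flagged <- screen_genes(many, one)
  expect_true(all(!flagged$stats_defined))
  expect_true(all(is.na(flagged$fold_change)))
})

test_that("strict cascade reproduces bundled panel membership row by row", {
  panel <- apply_strict_criteria(ccrcc_candidate_panel())
  expect_true("NDUFA4L2" %in% panel$strict$gene)
  cdk18 <- dplyr::filter(panel$relaxed, gene == "CDK18")
  expect_false(cdk18$strict_pass)
  expect_true(all(c("percentile_ratio", "blood_geo") %in% cdk18$failed_criteria[[1]]))
  # inclusive blood bound keeps the gene whose GEO p95 sits exactly on 1
  expect_true("CA9" %in% panel$strict$gene)

  empty <- apply_strict_criteria(ccrcc_candidate_panel()[0, ])
  expect_equal(nrow(empty$strict), 0L)
  expect_equal(nrow(empty$relaxed), 0L)
})

test_that("strict/relaxed split partitions the records", {
  records <- ccrcc_candidate_panel()
  panel <- apply_strict_criteria(records)
  combined <- tidy(panel)
  expect_setequal(combined$gene, records$gene)
  expect_equal(nrow(panel$strict) + nrow(panel$relaxed), nrow(records))
  expect_length(intersect(panel$strict$gene, panel$relaxed$gene), 0L)
  # ordering: descending tumor median within each part
  expect_true(all(diff(panel$strict$cancer_median) <= 0))
  expect_true(all(diff(panel$relaxed$cancer_median) <= 0))
  # strict rows failed nothing; relaxed rows failed at least one criterion
  expect_true(all(lengths(panel$strict$failed_criteria) == 0L))
  expect_true(all(lengths(panel$relaxed$failed_criteria) >= 1L))
})

test_that("relaxing any single threshold never shrinks the strict panel", {
  records <- ccrcc_candidate_panel()
  base <- screen_criteria()
  n0 <- nrow(apply_strict_criteria(records, base)$strict)
  variants <- list(
    screen_criteria(blood_p95_max = c(geo = 2, gtex = 2)),
    screen_criteria(fold_min = 0.5),
    screen_criteria(percentile_ratio_min = 0.25),
    screen_criteria(cancer_median_min = 1)
  )
  for (crit in variants) {
    expect_gte(nrow(apply_strict_criteria(records, crit)$strict), n0)
  }
  # tightening, for contrast, can only shrink it
  tight <- screen_criteria(cancer_median_min = 50)
  expect_lte(nrow(apply_strict_criteria(records, tight)$strict), n0)
})

test_that("undefined statistics and the promoted overlap bound fail genes", {
  rec <- tibble::tibble(
    gene = c("U", "V"),
    cancer_median = c(NA_real_, 50),
    fold_change = c(2, 2),
    percentile_ratio = c(1, 1),
    overlap_score = c(0.1, 0.9),
    blood_p95_geo = c(0, 0)
  )
  panel <- apply_strict_criteria(rec)
  expect_true("cancer_median" %in%
                panel$relaxed$failed_criteria[[which(panel$relaxed$gene == "U")]])
  hard <- apply_strict_criteria(rec, screen_criteria(overlap_is_hard = TRUE))
  v <- dplyr::filter(tidy(hard), gene == "V")
  expect_true("overlap" %in% v$failed_criteria[[1]])
})

test_that("panel reports round-trip through TSV", {
  panel <- apply_strict_criteria(ccrcc_candidate_panel())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_report(panel, path)
  lines <- readLines(path)
  expect_length(lines, 31 + 1)
  expect_match(lines[1], "^gene\tcancer_median_rpkm\tfold_change\tpercentile_ratio")

  back <- read_panel_report(path)
  orig <- tidy(panel)
  expect_equal(back$gene, orig$gene)
  expect_equal(back$cancer_median, orig$cancer_median)
  expect_equal(back$strict_pass, orig$strict_pass)
  expect_equal(back$failed_criteria, orig$failed_criteria)

  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_report(apply_strict_criteria(ccrcc_candidate_panel()[0, ]), empty_path)
  expect_length(readLines(empty_path), 1L)
})
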