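test_that("detectability filter retains genes with mean Cq below the ceiling", {
  fx <- ccrcc_detectability()
  keep <- detectability_filter(ccrcc_detectability_cq())
  expect_setequal(keep, fx$gene[fx$cq_status == "measured"])
  expect_length(keep, 9L)

  tb <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), 3),
    gene = rep(c("hi", "lo", "gone"), each = 2),
    cq = c(34, 34, 20, 20, NA, NA),
    group = "cancer"
  )
  expect_identical(detectability_filter(tb), "lo")
  expect_setequal(detectability_filter(tb, max_cq = 35), c("hi", "lo"))
})

test_that("technical replicates average on the Cq scale", {
  tb <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    gene = c("G", "G", "G", "G"),
    cq = c(30, 31, NA, 25),
    group = "cancer"
  )
  got <- average_technical_replicates(tb)
  expect_equal(nrow(got), 2L)
  expect_equal(got$cq[got$sample_id == "s1"], 30.5)
})

test_that("reference normalization subtracts per-sample reference Cq", {
  tb <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2"),
    gene = c("T", "PPIA", "T", "PPIA"),
    cq = c(30, 25, 26, 26),
    group = "normal"
  )
  got <- normalize_to_reference(tb)
  expect_setequal(got$gene, "T")
  expect_equal(got$cq, c(5, 0))
  expect_identical(attr(got, "reference_gene"), "PPIA")

  set.seed(61)
  rnd <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:6), each = 3),
    gene = rep(c("A", "B", "PPIA"), 6),
    cq = runif(18, 20, 35),
    group = rep(c("normal", "cancer"), each = 9)
  )
  got <- normalize_to_reference(rnd)
  ref <- rnd$cq[rnd$gene == "PPIA"]
  names(ref) <- rnd$sample_id[rnd$gene == "PPIA"]
  for (i in seq_len(nrow(got))) {
    raw <- rnd$cq[rnd$sample_id == got$sample_id[i] & rnd$gene == got$gene[i]]
    expect_equal(got$cq[i], raw - ref[[got$sample_id[i]]])
  }

  # a sample without reference measurement is dropped with a warning
  norf <- dplyr::filter(tb, !(sample_id == "s2" & gene == "PPIA"))
  expect_warning(dropped <- normalize_to_reference(norf), "s2")
  expect_setequal(dropped$sample_id, "s1")
  expect_error(normalize_to_reference(dplyr::filter(tb, gene != "PPIA")),
               class = "rccpanel_validation_error")
})

test_that("relative quantities follow the mean-anchored power-of-two formula", {
  expect_equal(relative_quantity(c(27, 28, 29)), c(2, 1, 0.5))
  expect_equal(relative_quantity(30), 1)
  expect_error(relative_quantity(c(NA_real_, NA_real_)),
               class = "rccpanel_validation_error")

  set.seed(62)
  for (i in 1:20) {
    v <- runif(sample(2:15, 1), 18, 35)
    rq <- relative_quantity(v)
    expect_equal(exp(mean(log(rq))), 1, tolerance = 1e-9)
  }
})

test_that("shifting every Cq of a gene leaves RQ, fold and p unchanged", {
  set.seed(63)
  tb <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    gene = "G",
    cq = rnorm(12, 28, 1),
    group = rep(c("normal", "cancer"), each = 6)
  )
  shifted <- dplyr::mutate(tb, cq = cq + 3.7)
  r1 <- compare_groups(tb)
  r2 <- compare_groups(shifted)
  expect_equal(r1$fold_change_signed, r2$fold_change_signed)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(add_relative_quantity(tb)$rq, add_relative_quantity(shifted)$rq)
})

test_that("group fold change is signed with magnitude at least one", {
  expect_equal(group_fold_change(rep(30, 3), rep(25, 4)), 32)
  expect_equal(group_fold_change(rep(25, 3), rep(30, 4)), -32)
  expect_equal(group_fold_change(c(27, 29), c(28, 28)), 1)

  set.seed(64)
  for (i in 1:20) {
    a <- rnorm(5, 28); b <- rnorm(7, 27)
    f <- group_fold_change(a, b)
    g <- group_fold_change(b, a)
    expect_gte(abs(f), 1)
    expect_equal(abs(f), abs(g))
    if (abs(f) > 1) expect_equal(sign(f), -sign(g))
  }
})

test_that("group comparison verdicts use the alpha and sign rule", {
  set.seed(65)
  tb <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:10), 1),
    gene = "G",
    cq = rep(c(28.1, 27.9, 28, 28.05, 27.95), 2),
    group = rep(c("normal", "cancer"), each = 5)
  )
  expect_identical(compare_groups(tb)$verdict, "ns")

  fx <- ccrcc_qpcr_results()
  expect_identical(qpcr_verdict(fx$fold_change_signed, fx$p_value, alpha = 0.05),
                   fx$verdict)

  # underpowered flag on tiny groups
  tiny <- tibble::tibble(
    sample_id = sprintf("s%d", 1:3), gene = "G",
    cq = c(28, 27, 26), group = c("normal", "cancer", "cancer")
  )
  expect_true(compare_groups(tiny)$underpowered)
})

test_that("a planted one-cycle shift is detected in nearly all replicates", {
  truth <- simulate_truth(1, n_planted = 1, planted_cq_shift = -1)
  verdicts <- vapply(1:40, function(s) {
    cq <- simulate_cq_experiment(truth, seed = 1000 + s)
    res <- compare_groups(normalize_to_reference(cq))
    res$verdict
  }, character(1))
  expect_gte(mean(verdicts == "down"), 0.95)
})

test_that("the metastatic-contrast grouping compares the two cancer strata", {
  truth <- simulate_truth(1, n_planted = 1, planted_cq_shift = 0)
  cq <- simulate_cq_experiment(truth, metastatic_extra_shift = 2, sd = 0.3, seed = 71)
  res <- compare_groups(normalize_to_reference(cq),
                        comparison = "nonmetastatic_vs_metastatic")
  expect_equal(res$n_baseline, 10L)
  expect_equal(res$n_case, 6L)
  expect_identical(res$verdict, "up")
  expect_error(compare_groups(cq, comparison = "bogus"),
               class = "rccpanel_validation_error")
})
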