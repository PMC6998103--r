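test_that("expression matrix TSV round-trips values and shape", {
  m <- make_expr(matrix(c(0, 1.5, 2, 3.25, 0.001, 7), nrow = 3),
                 gene_ids = c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path, unit = "rpkm")
  expect_equal(dim(back), c(3L, 3L))
  expect_identical(back$gene_id, c("A", "B", "C"))
  expect_equal(as.data.frame(back), as.data.frame(m))
  expect_identical(expr_unit(back), "rpkm")
})

test_that("malformed, negative and empty matrix files are rejected", {
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "A\t-1"), neg)
  expect_error(read_expression_matrix(neg), class = "rccpanel_validation_error")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_expression_matrix(empty), "empty", class = "rccpanel_io_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "A\tnot_a_number"), bad)
  expect_error(read_expression_matrix(bad), "line 2", class = "rccpanel_io_error")

  nohdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\ts1", "A\t1"), nohdr)
  expect_error(read_expression_matrix(nohdr), "gene_id", class = "rccpanel_io_error")
})

test_that("collapse_max merges aliased rows by elementwise maximum", {
  m <- make_expr(matrix(c(1, 2, 5, 3), nrow = 2), gene_ids = c("g1a", "g1b"))
  got <- collapse_max(m, c(g1a = "G1", g1b = "G1"))
  expect_identical(got$gene_id, "G1")
  expect_equal(unname(unlist(got[1, -1])), c(2, 5))

  # unmapped single row is untouched
  single <- make_expr(matrix(c(3, 4), nrow = 1), gene_ids = "solo")
  expect_equal(as.data.frame(collapse_max(single)), as.data.frame(single))
})

test_that("collapse_max equals per-cell max oracle and is idempotent", {
  set.seed(11)
  vals <- matrix(runif(24, 0, 50), nrow = 6)
  genes <- c("a1", "a2", "b1", "b2", "c", "d")
  amap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  m <- make_expr(vals, gene_ids = genes)
  got <- collapse_max(m, amap)
  canonical <- ifelse(genes %in% names(amap), amap[genes], genes)
  for (g in unique(canonical)) {
    rows <- which(canonical == g)
    expected <- apply(vals[rows, , drop = FALSE], 2, max)
    expect_equal(unname(unlist(got[got$gene_id == g, -1])), unname(expected))
    # every merged input cell is dominated
    for (r in rows) {
      expect_true(all(unlist(got[got$gene_id == g, -1]) >= vals[r, ]))
    }
  }
  expect_equal(as.data.frame(collapse_max(got)), as.data.frame(got))
})

test_that("alias maps with chains or conflicting targets are rejected", {
  m <- make_expr(matrix(1:4, nrow = 2), gene_ids = c("x", "y"))
  expect_error(collapse_max(m, c(x = "y", y = "z")),
               class = "rccpanel_validation_error")
  expect_error(
    collapse_max(m, data.frame(alias = c("x", "x"), gene_id = c("A", "B"))),
    class = "rccpanel_validation_error"
  )
})

test_that("average_per_subject averages within subject and group", {
  m <- make_expr(matrix(c(2, 4), nrow = 1), gene_ids = "G")
  meta <- tibble::tibble(
    sample_id = c("s1", "s2"), subject_id = "P1",
    group = "cancer", tissue = "kidney", source = "x"
  )
  got <- average_per_subject(m, meta)
  expect_equal(unname(unlist(got[1, -1])), 3)
  expect_identical(sample_ids(got), "P1")

  # one sample per subject: identity up to column naming
  meta1 <- meta[1, ]
  got1 <- average_per_subject(make_expr(matrix(2, nrow = 1), gene_ids = "G"), meta1)
  expect_equal(unname(unlist(got1[1, -1])), 2)
})

test_that("average_per_subject matches a direct group-mean oracle", {
  set.seed(21)
  vals <- matrix(runif(40, 0, 100), nrow = 5)
  m <- make_expr(vals)
  subj <- sample(c("P1", "P2", "P3"), 8, replace = TRUE)
  meta <- tibble::tibble(
    sample_id = sample_ids(m), subject_id = subj,
    group = "cancer", tissue = "kidney", source = "x"
  )
  got <- average_per_subject(m, meta)
  for (p in unique(subj)) {
    expected <- rowMeans(vals[, subj == p, drop = FALSE])
    expect_equal(unname(unlist(got[[p]])), unname(expected))
  }
  # per-gene grand totals weighted by subject sample counts are preserved
  counts <- table(subj)[sample_ids(got)]
  expect_equal(as.numeric(as.matrix(got[-1]) %*% as.numeric(counts)),
               unname(rowSums(vals)))
})

test_that("a subject spanning cancer and normal is never merged across groups", {
  m <- make_expr(matrix(c(10, 20, 30), nrow = 1), gene_ids = "G")
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    subject_id = c("P1", "P1", "P1"),
    group = c("cancer", "cancer", "normal"),
    tissue = "kidney", source = "x"
  )
  got <- average_per_subject(m, meta)
  expect_setequal(sample_ids(got), c("P1.cancer", "P1.normal"))
  expect_equal(got[["P1.cancer"]], 15)
  expect_equal(got[["P1.normal"]], 30)

  expect_error(average_per_subject(m, meta[1:2, ]),
               class = "rccpanel_validation_error")
})

test_that("compute_rpkm applies both formula variants", {
  m <- make_expr(matrix(c(10, 0), nrow = 2), gene_ids = c("A", "B"),
                 unit = "counts")
  ann <- data.frame(gene_id = c("A", "B"), length = c(1000, 500))
  lib <- c(s1 = 1e6)
  printed <- compute_rpkm(m, ann, mode = "as_printed", library_size = lib)
  expect_equal(printed$s1, c(0.01, 0))
  standard <- compute_rpkm(m, ann, mode = "standard", library_size = lib)
  expect_equal(standard$s1, c(10, 0))
  expect_identical(expr_unit(standard), "rpkm")

  expect_error(compute_rpkm(m, ann, library_size = c(s1 = 0)),
               class = "rccpanel_validation_error")
  expect_error(compute_rpkm(m, ann[1, ]), "B",
               class = "rccpanel_validation_error")
  expect_error(compute_rpkm(standard, ann), class = "rccpanel_validation_error")
})

test_that("rpkm is invariant when all counts and library sizes double", {
  set.seed(31)
  vals <- matrix(rpois(20, 40), nrow = 4)
  m <- make_expr(vals, unit = "counts")
  m2 <- make_expr(2 * vals, unit = "counts")
  ann <- data.frame(gene_id = m$gene_id, length = c(500, 1000, 2000, 1500))
  expect_equal(as.data.frame(compute_rpkm(m, ann)),
               as.data.frame(compute_rpkm(m2, ann)))
})

test_that("gene-set files parse, deduplicate and reject duplicate tissues", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("kidney\tA,B,C", "blood\tB\tB,D"), path)
  sets <- read_gene_sets(path)
  expect_identical(sets$kidney, c("A", "B", "C"))
  expect_identical(sets$blood, c("B", "D"))

  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("kidney\tA", "kidney\tB"), dup)
  expect_error(read_gene_sets(dup), class = "rccpanel_validation_error")
})
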