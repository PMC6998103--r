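#' Expression matrices as tibbles
#'
#' An expression matrix is represented as a tibble whose first column,
#' `gene_id`, holds gene identifiers and whose remaining columns hold one
#' nonnegative numeric vector per sample. The measurement unit
#' (`"counts"` for raw read counts or `"rpkm"` for reads per kilobase of
#' transcript per million mapped reads) travels with the object as an
#' attribute so downstream stages can refuse inputs on the wrong scale.
#'
#' Gene identifiers may be duplicated in a freshly loaded matrix
#' (isoforms, probe-level rows, alias spellings); [collapse_max()] merges
#' them. Sample identifiers must always be unique.
#'
#' @param data A data frame with a `gene_id` character column followed by
#'   numeric sample columns.
#' @param unit Measurement unit, `"counts"` or `"rpkm"`.
#' @return A tibble of class `expr_matrix` with a `unit` attribute.
#' @examples
#' m <- expr_matrix(
#'   data.frame(gene_id = c("A", "B"), s1 = c(1, 0), s2 = c(2.5, 4)),
#'   unit = "rpkm"
#' )
#' expr_unit(m)
#' @export
expr_matrix <- function(data, unit = c("rpkm", "counts")) {
  unit <- match.arg(unit)
  data <- as_tibble(data)
  if (ncol(data) < 2L || names(data)[1] != "gene_id") {
    abort_validation("an expression matrix needs a leading 'gene_id' column and at least one sample column")
  }
  if (anyDuplicated(names(data)[-1])) {
    abort_validation(sprintf(
      "duplicate sample ids: %s",
      oxford(unique(names(data)[-1][duplicated(names(data)[-1])]))
    ))
  }
  data$gene_id <- as.character(data$gene_id)
  num_ok <- vapply(data[-1], is.numeric, logical(1))
  if (!all(num_ok)) {
    abort_validation(sprintf(
      "non-numeric sample columns: %s", oxford(names(data)[-1][!num_ok])
    ))
  }
  vals <- as.matrix(data[-1])
  if (anyNA(vals)) {
    abort_validation("expression values must not be missing")
  }
  if (any(vals < 0)) {
    bad <- data$gene_id[which(rowSums(vals < 0) > 0)]
    abort_validation(sprintf("negative expression values for genes: %s", oxford(unique(bad))))
  }
  structure(data, unit = unit, class = c("expr_matrix", class(data)))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_unit <- function(x) {
  attr(x, "unit") %||% abort_validation("object carries no unit attribute; is it an expr_matrix?")
}

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) names(x)[-1]

# Numeric sample block as a base matrix with gene_id rownames (duplicates
# allowed; rownames then repeat).
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

assert_unit <- function(x, unit, what = "matrix") {
  if (!identical(expr_unit(x), unit)) {
    abort_validation(sprintf("%s must be in %s (got %s)", what, unit, expr_unit(x)))
  }
  invisible(x)
}

#' Read and write expression matrix TSV files
#'
#' The on-disk dialect is UTF-8 tab-separated values with a header row of
#' sample identifiers, a first header cell `gene_id`, and `.` as the
#' decimal separator. Duplicate gene rows are preserved on read; merging
#' is a separate, explicit step ([collapse_max()]).
#'
#' @param path Path to a TSV file.
#' @param unit Declared unit of the stored values (`"rpkm"` or
#'   `"counts"`).
#' @return [read_expression_matrix()] returns an [expr_matrix()];
#'   [write_expression_matrix()] invisibly returns `path`.
#' @export
read_expression_matrix <- function(path, unit = c("rpkm", "counts")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort_io(sprintf("expression matrix file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    abort_io(sprintf("parse error in %s: file is empty (line 1)", path))
  }
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene_id") {
    abort_io(sprintf("parse error in %s (line 1): header must start with 'gene_id' and name at least one sample", path))
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- suppressWarnings(readr::problems(raw))
  if (nrow(probs) > 0L) {
    # problems() rows count the header line, i.e. they are physical lines
    abort_io(sprintf(
      "parse error in %s (line %d): expected %s", path, probs$row[1], probs$expected[1]
    ))
  }
  expr_matrix(raw, unit = unit)
}

#' @rdname read_expression_matrix
#' @param x An `expr_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- tryCatch(
    readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE),
    error = function(e) abort_io(sprintf("cannot write expression matrix to %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `subject_id`, `group`
#' (`cancer`, `normal`, `blood` or `other`), `tissue` and `source`. Every
#' sample column of an accompanying expression matrix must have exactly
#' one metadata row.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with the five metadata columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("metadata file not found: %s", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  validate_sample_metadata(meta)
}

validate_sample_metadata <- function(meta) {
  meta <- as_tibble(meta)
  needed <- c("sample_id", "subject_id", "group", "tissue", "source")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    abort_validation(sprintf("metadata is missing columns: %s", oxford(missing)))
  }
  bad <- setdiff(unique(meta$group), c("cancer", "normal", "blood", "other"))
  if (length(bad)) {
    abort_validation(sprintf("unknown metadata group(s): %s", oxford(bad)))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort_validation(sprintf(
      "duplicated sample_id in metadata: %s",
      oxford(unique(meta$sample_id[duplicated(meta$sample_id)]))
    ))
  }
  meta[needed]
}

#' Merge duplicate gene rows by elementwise maximum
#'
#' Expression tables assembled from several annotation layers often carry
#' one gene under multiple rows: isoform entries, duplicate symbols, or
#' alias spellings. To avoid underestimating a gene's possible presence
#' (which matters most when screening blood for absence), duplicates are
#' merged by taking, per sample, the absolute highest value across the
#' merged rows.
#'
#' @param x An [expr_matrix()].
#' @param alias_map Optional mapping of row identifiers onto canonical
#'   gene ids: either a named character vector (names = aliases, values =
#'   canonical ids) or a data frame with columns `alias` and `gene_id`.
#'   Rows not covered by the map keep their own identifier. Passing
#'   `NULL` merges only rows that already share a `gene_id`.
#' @return An `expr_matrix` with unique `gene_id`s, same unit, rows
#'   ordered by first appearance of each canonical id.
#' @examples
#' m <- expr_matrix(data.frame(gene_id = c("g1a", "g1b"),
#'                             s1 = c(1, 2), s2 = c(5, 3)), unit = "rpkm")
#' collapse_max(m, c(g1a = "G1", g1b = "G1"))
#' @export
collapse_max <- function(x, alias_map = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  map <- normalize_alias_map(alias_map)
  canon <- x$gene_id
  if (length(map)) {
    hit <- canon %in% names(map)
    canon[hit] <- unname(map[canon[hit]])
  }
  vals <- expr_values(x)
  ids <- unique(canon)
  groups <- split(seq_along(canon), factor(canon, levels = ids))
  agg <- t(vapply(groups, function(i) {
    apply(vals[i, , drop = FALSE], 2, max)
  }, numeric(ncol(vals))))
  if (ncol(vals) == 1L) agg <- matrix(agg, ncol = 1L, dimnames = list(ids, colnames(vals)))
  expr_matrix(tibble(gene_id = ids, as_tibble(agg)), unit = expr_unit(x))
}

normalize_alias_map <- function(alias_map) {
  if (is.null(alias_map)) return(character())
  if (is.data.frame(alias_map)) {
    if (!all(c("alias", "gene_id") %in% names(alias_map))) {
      abort_validation("alias_map data frame needs columns 'alias' and 'gene_id'")
    }
    alias_map <- setNames(as.character(alias_map$gene_id), as.character(alias_map$alias))
  }
  if (!is.character(alias_map) || is.null(names(alias_map)) || any(!nzchar(names(alias_map)))) {
    abort_validation("alias_map must be a named character vector or an alias/gene_id data frame")
  }
  if (anyDuplicated(names(alias_map))) {
    abort_validation(sprintf(
      "alias mapped to multiple targets: %s",
      oxford(unique(names(alias_map)[duplicated(names(alias_map))]))
    ))
  }
  # A canonical target that is itself an alias of something else would make
  # the collapse order-dependent; identity self-maps are fine.
  proper <- alias_map[alias_map != names(alias_map)]
  chained <- intersect(unname(proper), names(proper))
  if (length(chained)) {
    abort_validation(sprintf("alias map contains chained/cyclic entries via: %s", oxford(chained)))
  }
  alias_map
}

#' Average expression over samples of the same subject
#'
#' Cohorts frequently hold several specimens per patient. Per-gene
#' arithmetic means are taken over each subject's samples, separately
#' within each metadata group: a patient contributing both a tumor and a
#' matched-normal specimen yields one averaged cancer column and one
#' averaged normal column, never a cross-group blend.
#'
#' @param x An [expr_matrix()].
#' @param meta Metadata tibble (see [read_sample_metadata()]) covering
#'   every sample column of `x`.
#' @return An `expr_matrix` with one column per (subject, group). The
#'   column is named by `subject_id` when the subject occurs in a single
#'   group and `subject_id.group` otherwise; the mapping is attached as
#'   attribute `sample_meta` (a tibble with `sample_id`, `subject_id`,
#'   `group`).
#' @export
average_per_subject <- function(x, meta) {
  stopifnot(inherits(x, "expr_matrix"))
  meta <- validate_sample_metadata(meta)
  missing <- setdiff(sample_ids(x), meta$sample_id)
  if (length(missing)) {
    abort_validation(sprintf("samples without metadata: %s", oxford(missing)))
  }
  if (anyNA(meta$subject_id) || any(!nzchar(meta$subject_id))) {
    abort_validation("every sample needs a subject_id for per-subject averaging")
  }
  meta <- meta %>% filter(.data$sample_id %in% sample_ids(x))
  key <- meta %>%
    distinct(.data$subject_id, .data$group) %>%
    group_by(.data$subject_id) %>%
    mutate(multi = n() > 1L) %>%
    ungroup() %>%
    mutate(column = if_else(.data$multi, paste(.data$subject_id, .data$group, sep = "."),
                            .data$subject_id))
  meta2 <- left_join(meta, key, by = c("subject_id", "group"))
  vals <- expr_values(x)
  cols <- unique(meta2$column)
  avg <- vapply(cols, function(cl) {
    s <- meta2$sample_id[meta2$column == cl]
    rowMeans(vals[, s, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) avg <- matrix(avg, nrow = 1L, dimnames = list(NULL, cols))
  out <- expr_matrix(tibble(gene_id = x$gene_id, as_tibble(avg)), unit = expr_unit(x))
  attr(out, "sample_meta") <- key %>%
    select(sample_id = "column", subject_id = "subject_id", group = "group")
  out
}

#' RPKM normalization of a raw count matrix
#'
#' Converts raw read counts to reads per kilobase of transcript per
#' million mapped reads. Two variants are provided. `"standard"` (the
#' default) is the conventional definition,
#' \deqn{rpkm = count \times 10^9 / (length \times library\ size),}
#' i.e. counts scaled per kilobase of gene length and per million mapped
#' reads. `"as_printed"` drops the per-kilobase factor of 1,000,
#' \eqn{count \times 10^6 / (length \times library\ size)}, a reduced
#' variant occasionally seen in screening pipelines; it rescales every
#' gene by a constant, so threshold-based screens shift with it. The two
#' differ by exactly 1,000.
#'
#' @param x An [expr_matrix()] in counts.
#' @param annotation Data frame with columns `gene_id` and `length`
#'   (transcript length in bases, >= 1).
#' @param mode `"standard"` or `"as_printed"`.
#' @param library_size Optional named numeric vector of per-sample mapped
#'   read totals; defaults to the column sums of `x`.
#' @return An `expr_matrix` in rpkm with the same dimensions.
#' @examples
#' m <- expr_matrix(data.frame(gene_id = "A", s1 = 10), unit = "counts")
#' ann <- data.frame(gene_id = "A", length = 1000)
#' compute_rpkm(m, ann, library_size = c(s1 = 1e6))            # 10
#' compute_rpkm(m, ann, mode = "as_printed",
#'              library_size = c(s1 = 1e6))                    # 0.01
#' @export
compute_rpkm <- function(x, annotation, mode = c("standard", "as_printed"),
                         library_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expr_matrix"))
  assert_unit(x, "counts", "count matrix")
  annotation <- as_tibble(annotation)
  if (!all(c("gene_id", "length") %in% names(annotation))) {
    abort_validation("annotation needs columns 'gene_id' and 'length'")
  }
  if (any(annotation$length < 1)) {
    abort_validation("gene lengths must be >= 1 base")
  }
  len <- setNames(as.numeric(annotation$length), annotation$gene_id)
  missing <- setdiff(unique(x$gene_id), names(len))
  if (length(missing)) {
    abort_validation(sprintf("no gene length for: %s", oxford(missing)))
  }
  vals <- expr_values(x)
  if (is.null(library_size)) {
    library_size <- colSums(vals)
  } else {
    absent <- setdiff(colnames(vals), names(library_size))
    if (length(absent)) {
      abort_validation(sprintf("library_size missing for samples: %s", oxford(absent)))
    }
    library_size <- library_size[colnames(vals)]
  }
  if (any(library_size <= 0)) {
    abort_validation(sprintf(
      "zero or negative library size for samples: %s",
      oxford(colnames(vals)[library_size <= 0])
    ))
  }
  scale <- if (mode == "standard") 1e9 else 1e6
  rpkm <- sweep(vals / len[x$gene_id], 2, library_size, `/`) * scale
  expr_matrix(tibble(gene_id = x$gene_id, as_tibble(rpkm)), unit = "rpkm")
}

#' Read tissue gene-set files
#'
#' A GMT-like dialect: one tissue per line, tissue name first, then a tab
#' and the member gene symbols separated by commas or further tabs.
#' Symbols are deduplicated per tissue; a tissue appearing on two lines
#' is an error (sets are written whole, not incrementally).
#'
#' @param path Path to the gene-set file.
#' @return A named list of character vectors (tissue -> gene symbols).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("gene-set file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  parsed <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tissue <- trimws(fields[1])
    if (!nzchar(tissue)) abort_io(sprintf("gene-set line without tissue name: %s", ln))
    syms <- unlist(strsplit(fields[-1], ",", fixed = TRUE), use.names = FALSE)
    syms <- unique(trimws(syms))
    syms <- syms[nzchar(syms)]
    list(tissue = tissue, symbols = syms)
  })
  tissues <- vapply(parsed, `[[`, character(1), "tissue")
  if (anyDuplicated(tissues)) {
    abort_validation(sprintf(
      "tissue listed more than once: %s", oxford(unique(tissues[duplicated(tissues)]))
    ))
  }
  setNames(lapply(parsed, `[[`, "symbols"), tissues)
}
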