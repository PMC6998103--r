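# Independent oracles used by the property tests. Each re-derives the
# quantity from first principles, without calling the package's
# implementation path.

# Linear interpolation between closest order statistics, written out
# explicitly (shared percentile convention).
oracle_percentile <- function(x, q) {
  s <- unname(sort(x))
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * q / 100
  lo <- floor(h)
  if (lo == n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Brute-force two-sample overlap score: closed overlap interval of the
# ranges, per-sample inside-counts, with the three definitional
# overrides re-derived independently.
oracle_overlap <- function(a, b) {
  lo <- max(min(a), min(b))
  hi <- min(max(a), max(b))
  if (lo > hi) return(0)
  if (identical(sort(as.numeric(a)), sort(as.numeric(b)))) return(1)
  ina <- sum(vapply(a, function(v) v >= lo && v <= hi, logical(1)))
  inb <- sum(vapply(b, function(v) v >= lo && v <= hi, logical(1)))
  if (min(b) > min(a) && max(b) < max(a) && ina == 0) return(1)
  if (min(a) > min(b) && max(a) < max(b) && inb == 0) return(1)
  (ina / length(a)) * (inb / length(b))
}

# Sorted-middle median, avoiding stats::median.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Small expression matrix constructor for tests.
make_expr <- function(values, gene_ids = NULL, unit = "rpkm") {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expr_matrix(
    tibble::tibble(gene_id = gene_ids, tibble::as_tibble(values)),
    unit = unit
  )
}
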