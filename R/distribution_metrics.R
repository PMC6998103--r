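#' Percentile with a fixed interpolation convention
#'
#' All percentile-based statistics in the package share one convention:
#' linear interpolation between the closest order statistics
#' (`stats::quantile()` type 7). Fixing it in a single place keeps the
#' screening statistics, the blood summaries and every test oracle on
#' the same scale.
#'
#' @param values Non-empty numeric sample (missing values are an error).
#' @param q Percentile in `[0, 100]`.
#' @return The interpolated percentile.
#' @examples
#' pctl(0:100, 5)   # 5
#' pctl(c(7, 7, 7), 50)
#' @export
pctl <- function(values, q) {
  if (length(values) == 0L) abort_validation("percentile of an empty sample is undefined")
  if (anyNA(values)) abort_validation("percentile input contains missing values")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 100) {
    abort_validation("q must be a single value in [0, 100]")
  }
  quantile(as.numeric(values), q / 100, type = 7, names = FALSE)
}

#' Percentile-ratio distance between tumor and normal distributions
#'
#' The ratio of the 5th percentile of the tumor (cancer) expression
#' distribution to the 95th percentile of the matched-normal
#' distribution. Values above 1 mean the bulk of the two distributions
#' barely overlap; values above 0.5 are conventionally considered a
#' favorable separation for biomarker screening.
#'
#' A zero 95th percentile in the normal sample leaves the ratio
#' undefined; `NA` is returned (with attribute `undefined = TRUE`) so
#' that callers record the gene as not favorable rather than failing.
#'
#' @param cancer,normal Non-empty numeric samples.
#' @return A single nonnegative ratio, or `NA` when undefined.
#' @examples
#' percentile_ratio_distance(rep(10, 4), rep(5, 4))  # 2
#' @export
percentile_ratio_distance <- function(cancer, normal) {
  p5 <- pctl(cancer, 5)
  p95 <- pctl(normal, 95)
  if (p95 == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  p5 / p95
}

#' Two-sample overlap score
#'
#' A distribution-distance score in `[0, 1]` built from the closed
#' overlap interval of the two samples' ranges,
#' `[max(min(a), min(b)), min(max(a), max(b))]`. Each sample contributes
#' the probability of its observations falling within that interval
#' (`count inside / sample size`) and the score is the product of the
#' two probabilities: 0 means fully separated distributions, values near
#' 1 mean indistinguishable (or uninformative) ones. Favorable
#' separation for screening is conventionally a score below 0.3.
#'
#' Three special cases are fixed by definition:
#' \itemize{
#'   \item ranges that do not overlap score 0;
#'   \item identical samples (equal multisets) score 1;
#'   \item when one sample's range lies strictly inside the other's and
#'     the outer sample has no observations inside the closed overlap
#'     interval (its mass sits on both sides of it), the score is 1 —
#'     such genes cannot separate the groups and must not be rewarded
#'     with a small product.
#' }
#'
#' @param a,b Non-empty numeric samples.
#' @return A score in `[0, 1]`.
#' @examples
#' overlap_score(c(1, 2), c(5, 6))         # disjoint -> 0
#' overlap_score(c(1, 2, 3), c(1, 2, 3))   # identical -> 1
#' overlap_score(c(0, 10), c(4, 5, 6))     # containment override -> 1
#' overlap_score(1:4, 3:6)                 # (2/4) * (2/4) = 0.25
#' @export
overlap_score <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_validation("overlap score of an empty sample is undefined")
  }
  if (anyNA(a) || anyNA(b)) abort_validation("overlap score input contains missing values")
  lo <- max(min(a), min(b))
  hi <- min(max(a), max(b))
  if (lo > hi) return(0)
  if (identical(sort(as.numeric(a)), sort(as.numeric(b)))) return(1)
  inside_a <- sum(a >= lo & a <= hi)
  inside_b <- sum(b >= lo & b <= hi)
  # Strict range containment with no outer-sample mass inside the overlap
  # interval: the outer distribution straddles the inner one.
  a_inside_b <- min(a) > min(b) && max(a) < max(b)
  b_inside_a <- min(b) > min(a) && max(b) < max(a)
  if ((b_inside_a && inside_a == 0L) || (a_inside_b && inside_b == 0L)) return(1)
  (inside_a / length(a)) * (inside_b / length(b))
}

#' Median fold change between two samples
#'
#' `median(cancer) / median(normal)`. A zero normal median leaves the
#' ratio undefined; `NA` with attribute `undefined = TRUE` is returned.
#'
#' @param cancer,normal Non-empty numeric samples.
#' @return A positive ratio, or `NA` when undefined.
#' @export
median_fold_change <- function(cancer, normal) {
  if (length(cancer) == 0L || length(normal) == 0L) {
    abort_validation("fold change of an empty sample is undefined")
  }
  mn <- median(normal)
  if (mn == 0) return(structure(NA_real_, undefined = TRUE))
  median(cancer) / mn
}

#' Two-sided Mann-Whitney U test p-value
#'
#' Wraps [stats::wilcox.test()]. The exact null distribution is used
#' when the smaller group has at most `exact_max` observations and there
#' are no ties (enumeration is cheap there); otherwise the tie-corrected
#' normal approximation with continuity correction is used. When every
#' value in both groups is identical the test statistic is degenerate
#' and `p = 1` is returned by convention.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact_max Largest min-group size for which the exact
#'   distribution is used (default 8).
#' @return A two-sided p-value in `[0, 1]`.
#' @examples
#' mann_whitney_p(c(1, 2, 3), c(10, 11, 12))  # 0.1 (exact, C(6,3) = 20)
#' @export
mann_whitney_p <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_validation("Mann-Whitney test needs a value in each group")
  }
  if (anyNA(a) || anyNA(b)) abort_validation("Mann-Whitney input contains missing values")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- !has_ties && min(length(a), length(b)) <= exact_max
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact, correct = TRUE)$p.value
  )
  min(p, 1)
}
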