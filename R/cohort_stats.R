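#' @importFrom stats chisq.test cor.test median qlnorm pnorm rlnorm
#'   rnorm runif wilcox.test
NULL

test_result <- function(statistic, p_value, method) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  list(statistic = unname(statistic), p_value = unname(p_value),
       method = method)
}

#' Spearman rank correlation with mid-ranks for ties
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' p-value uses the t-distribution approximation. Used for the association
#' between matched plasma and urine cfDNA concentrations.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, no missing values.
#' @return List with `statistic` (rho), `p_value`, `method`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  test_result(ct$estimate, ct$p.value,
              "Spearman rank correlation; mid-ranks; t approximation")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided. Zero differences are dropped; tied absolute differences
#' receive mid-ranks. The exact null distribution is used when the number of
#' non-zero differences is below 50 and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return List with `statistic` (V), `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("degenerate input: all paired differences zero")
  if (length(d) < 3L) stop("need >= 3 non-zero differences")
  exact <- length(d) < 50 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  test_result(wt$statistic, wt$p.value, paste0(
    "Wilcoxon signed-rank, two-sided; zeros dropped; ",
    if (exact) "exact null distribution"
    else "normal approximation with tie and continuity correction"))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic with expected counts from the margins, df = (r-1)(c-1),
#' no continuity correction. Used to compare the per-fluid classification
#' distributions.
#'
#' @param table r x c matrix of non-negative counts with positive row and
#'   column sums.
#' @return List with `statistic`, `p_value`, `df`, `method`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  out <- test_result(ct$statistic, ct$p.value,
                     "Pearson chi-square, no continuity correction")
  out$df <- unname(ct$parameter)
  out
}

#' Median and range of a numeric vector
#'
#' Median uses the even-count-average convention.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `min`, `max`.
#' @export
median_range <- function(values) {
  if (length(values) == 0L || anyNA(values)) stop("non-empty values required")
  list(median = stats::median(values), min = min(values), max = max(values))
}
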