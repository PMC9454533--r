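#' Venn decomposition from per-fluid totals and the shared count
#'
#' Given the two per-fluid variant totals and the number of variants shared
#' between the fluids, returns the exclusive counts and the grand total,
#' enforcing Venn conservation (per-fluid total = exclusive + shared; grand
#' total = sum of per-fluid totals = a-exclusive + b-exclusive + 2 x shared).
#'
#' @param total_a,total_b Per-fluid variant totals.
#' @param shared Number of variant keys found in both fluids.
#' @return List with `a_exclusive`, `b_exclusive`, `shared`, `total_a`,
#'   `total_b`, `grand_total`.
#' @export
venn_from_totals <- function(total_a, total_b, shared) {
  if (shared > min(total_a, total_b))
    stop("shared count exceeds a per-fluid total")
  out <- list(a_exclusive = total_a - shared, b_exclusive = total_b - shared,
              shared = shared, total_a = total_a, total_b = total_b,
              grand_total = total_a + total_b)
  stopifnot(out$a_exclusive + out$shared == total_a,
            out$b_exclusive + out$shared == total_b,
            out$a_exclusive + out$b_exclusive + 2 * shared == out$grand_total)
  out
}

#' Percentage of a count within a denominator, at printing precision
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimal places of the printed percentage (default 1).
#' @return Numeric percentage(s) rounded to `digits`.
#' @export
percent_of <- function(n, total, digits = 1) {
  if (total <= 0) stop("percentage undefined for non-positive total")
  round(100 * n / total, digits)
}

#' Bundled printed cfDNA concentration table
#'
#' The 15-patient matched plasma/urine cfDNA concentration table shipped
#' with the package (ng/mL; urine zeros are real undetectable measurements).
#'
#' @return Data frame with columns patient_id, plasma_ng_ml, urine_ng_ml.
#' @export
study_concentrations <- function() {
  read_concentrations(system.file("extdata", "tnbc_cfdna_concentrations.csv",
                                  package = "ctdnaconcord", mustWork = TRUE))
}

#' Bundled printed five-class variant counts per fluid
#'
#' The published plasma/urine counts of pathogenic, likely pathogenic, VUS,
#' likely benign and benign variants, as a 2 x 5 matrix suitable for
#' [chi_square_independence()].
#'
#' @return Integer matrix with rows plasma/urine and the five class columns.
#' @export
study_class_counts <- function() {
  df <- utils::read.csv(system.file("extdata", "tnbc_class_counts.csv",
                                    package = "ctdnaconcord", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, ACMG_CLASSES])
  rownames(m) <- df$fluid
  storage.mode(m) <- "integer"
  m
}
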