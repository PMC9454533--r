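#' Recovery rate of one variant set in another
#'
#' Percentage of `source_keys` also present in `target_keys`:
#' `100 * |source intersect target| / |source|`. Undefined (NA) when the
#' source set is empty; undefined values are dropped, not zero-filled,
#' before cohort medians are taken.
#'
#' @param source_keys,target_keys Character vectors of normalized variant
#'   keys.
#' @return Percent in \[0, 100\], or NA for an empty source.
#' @export
recovery_rate <- function(source_keys, target_keys) {
  source_keys <- unique(source_keys)
  if (length(source_keys) == 0L) return(NA_real_)
  100 * length(intersect(source_keys, target_keys)) / length(source_keys)
}

#' Matched-fluid concordance for one patient
#'
#' Intersects the plasma and urine survivor sets of one patient by normalized
#' variant key. Shared-variant identity is key equality only: VAF, quality
#' and annotations are attributes, not identity. The pathogenic-restricted
#' sets use the ACMG class called in the source fluid; a variant pathogenic
#' in plasma counts as recovered if its key is present in urine regardless of
#' the urine call's class.
#'
#' @param plasma_variants,urine_variants Classified survivor tables for the
#'   two fluids (must carry `key`; `acmg_class` enables the
#'   pathogenic-restricted sets).
#' @param patient_id Patient label.
#' @return A list of class `concordance_pair`: key sets (`plasma_set`,
#'   `urine_set`, `shared`, `plasma_exclusive`, `urine_exclusive`),
#'   recovery rates `recovery_pu` (plasma in urine) and `recovery_up`, and
#'   the same fields restricted to pathogenic calls (`path_*`).
#' @export
match_pair <- function(plasma_variants, urine_variants, patient_id = NA) {
  p <- plasma_variants$key
  u <- urine_variants$key
  if (anyDuplicated(p) || anyDuplicated(u))
    stop("duplicate normalized variant keys within one sample")
  shared <- intersect(p, u)
  path_keys <- function(v) {
    if (!"acmg_class" %in% names(v)) return(character(0))
    v$key[v$acmg_class == "pathogenic"]
  }
  pp <- path_keys(plasma_variants)
  up <- path_keys(urine_variants)
  pair <- list(
    patient_id = patient_id,
    plasma_set = p, urine_set = u, shared = shared,
    plasma_exclusive = setdiff(p, u), urine_exclusive = setdiff(u, p),
    recovery_pu = recovery_rate(p, u), recovery_up = recovery_rate(u, p),
    path_plasma_set = pp, path_urine_set = up,
    path_shared = intersect(pp, up),
    path_recovery_pu = recovery_rate(pp, u),
    path_recovery_up = recovery_rate(up, p)
  )
  stopifnot(length(pair$plasma_exclusive) + length(shared) == length(p),
            length(pair$urine_exclusive) + length(shared) == length(u))
  structure(pair, class = "concordance_pair")
}

count_table <- function(values, levels) {
  tab <- table(factor(values, levels = levels))
  as.integer(tab)
}

#' Cohort-level aggregation of matched-pair concordance
#'
#' Aggregates per-patient concordance pairs and the pooled classified
#' survivor table into the cohort summary: per-fluid totals and per-sample
#' counts with medians, Venn totals (fluid-exclusive and shared counts summed
#' over patients), recovery-rate medians (overall and pathogenic-only,
#' undefined rates dropped), VAF-bin/class/tier distribution tables per
#' fluid, a per-gene table (variant count and number of samples altered per
#' fluid, sorted by total count descending, ties by symbol) and the
#' pathogenic presence matrix.
#'
#' Medians use the even-count-average convention throughout.
#'
#' @param pairs List of `concordance_pair` objects.
#' @param variants Pooled classified survivor data frame for all samples
#'   (both fluids).
#' @return A list of class `cohort_summary`.
#' @export
cohort_summarize <- function(pairs, variants) {
  stopifnot(length(pairs) >= 1L)
  per_sample <- data.frame(
    patient_id = vapply(pairs, function(p) as.character(p$patient_id),
                        character(1)),
    n_plasma = vapply(pairs, function(p) length(p$plasma_set), integer(1)),
    n_urine = vapply(pairs, function(p) length(p$urine_set), integer(1)),
    n_shared = vapply(pairs, function(p) length(p$shared), integer(1)),
    recovery_pu = vapply(pairs, function(p) p$recovery_pu, numeric(1)),
    recovery_up = vapply(pairs, function(p) p$recovery_up, numeric(1)),
    path_recovery_pu = vapply(pairs, function(p) p$path_recovery_pu,
                              numeric(1)),
    path_recovery_up = vapply(pairs, function(p) p$path_recovery_up,
                              numeric(1)),
    stringsAsFactors = FALSE
  )
  venn <- list(
    plasma_total = sum(per_sample$n_plasma),
    urine_total = sum(per_sample$n_urine),
    shared = sum(per_sample$n_shared),
    plasma_exclusive = sum(per_sample$n_plasma - per_sample$n_shared),
    urine_exclusive = sum(per_sample$n_urine - per_sample$n_shared)
  )
  venn$grand_total <- venn$plasma_total + venn$urine_total
  stopifnot(venn$plasma_exclusive + venn$shared == venn$plasma_total,
            venn$urine_exclusive + venn$shared == venn$urine_total)

  med <- function(x) stats::median(x[!is.na(x)])
  medians <- list(
    plasma_per_sample = med(per_sample$n_plasma),
    urine_per_sample = med(per_sample$n_urine),
    shared_per_sample = med(per_sample$n_shared),
    recovery_pu = med(per_sample$recovery_pu),
    recovery_up = med(per_sample$recovery_up),
    path_recovery_pu = med(per_sample$path_recovery_pu),
    path_recovery_up = med(per_sample$path_recovery_up)
  )

  dist_tables <- function(fluid) {
    v <- variants[variants$fluid == fluid, , drop = FALSE]
    list(
      vaf_bins = count_table(as.character(v$vaf_bin), VAF_BIN_LABELS),
      classes = count_table(v$acmg_class, ACMG_CLASSES),
      tiers = count_table(v$tier, TIERS)
    )
  }
  plasma_tabs <- dist_tables("plasma")
  urine_tabs <- dist_tables("urine")

  gene_table <- gene_summary(variants)
  summary <- list(
    per_sample = per_sample, venn = venn, medians = medians,
    vaf_bins = data.frame(bin = VAF_BIN_LABELS,
                          plasma = plasma_tabs$vaf_bins,
                          urine = urine_tabs$vaf_bins),
    class_dist = data.frame(class = ACMG_CLASSES,
                            plasma = plasma_tabs$classes,
                            urine = urine_tabs$classes),
    tier_dist = data.frame(tier = TIERS,
                           plasma = plasma_tabs$tiers,
                           urine = urine_tabs$tiers),
    gene_table = gene_table,
    pathogenic_matrix = pathogenic_matrix(variants)
  )
  structure(summary, class = "cohort_summary")
}

gene_summary <- function(variants) {
  out <- data.frame(gene = character(0), plasma_variants = integer(0),
                    urine_variants = integer(0), total = integer(0),
                    plasma_samples = integer(0), urine_samples = integer(0),
                    stringsAsFactors = FALSE)
  v <- variants[!is.na(variants$gene), , drop = FALSE]
  if (nrow(v) == 0L) return(out)
  genes <- sort(unique(v$gene))
  cnt <- function(fluid) vapply(genes, function(g)
    sum(v$gene == g & v$fluid == fluid), integer(1))
  nsamp <- function(fluid) vapply(genes, function(g)
    length(unique(v$sample_id[v$gene == g & v$fluid == fluid])), integer(1))
  out <- data.frame(gene = genes,
                    plasma_variants = cnt("plasma"),
                    urine_variants = cnt("urine"),
                    plasma_samples = nsamp("plasma"),
                    urine_samples = nsamp("urine"),
                    stringsAsFactors = FALSE)
  out$total <- out$plasma_variants + out$urine_variants
  # sort by total count descending, ties broken by symbol (already sorted)
  out <- out[order(-out$total, out$gene), ]
  rownames(out) <- NULL
  out[, c("gene", "plasma_variants", "urine_variants", "total",
          "plasma_samples", "urine_samples")]
}

#' Presence matrix of pathogenic variants across samples
#'
#' Rows are distinct pathogenic variant keys (labelled gene:key), columns are
#' sample-by-fluid combinations, cells are 0/1 presence. Rows are ordered by
#' the number of positive samples, descending (ties by label), so a variant
#' found in every sample ranks first.
#'
#' @param variants Pooled classified variant data frame.
#' @return Integer matrix (possibly 0-row) with dimnames.
#' @export
pathogenic_matrix <- function(variants) {
  path <- variants[variants$acmg_class == "pathogenic", , drop = FALSE]
  samples <- unique(variants[, c("sample_id", "fluid")])
  samples <- samples[order(samples$sample_id, samples$fluid), , drop = FALSE]
  cols <- paste(samples$sample_id, samples$fluid, sep = "_")
  if (nrow(path) == 0L)
    return(matrix(integer(0), nrow = 0, ncol = length(cols),
                  dimnames = list(character(0), cols)))
  label <- paste(ifelse(is.na(path$gene), ".", path$gene), path$key, sep = ":")
  rows <- sort(unique(label))
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  col_of <- paste(path$sample_id, path$fluid, sep = "_")
  for (i in seq_len(nrow(path)))
    m[match(label[i], rows), match(col_of[i], cols)] <- 1L
  m <- m[order(-rowSums(m), rownames(m)), , drop = FALSE]
  m
}
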