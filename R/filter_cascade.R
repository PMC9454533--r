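#' Filter cascade thresholds
#'
#' Thresholds for the three-stage somatic variant filter cascade. All
#' thresholds are inclusive on the keep side: a variant survives the
#' confidence filter with call quality >= 50 and VAF >= 3%, survives the
#' common-variant filter with population allele fraction <= 1%, and survives
#' the intronic-distance criterion with |offset| <= 20 bases.
#'
#' @param min_call_quality Minimum phred-scaled call quality kept (default 50).
#' @param min_vaf_pct Minimum VAF in percent kept (default 3).
#' @param max_pop_af Maximum population allele fraction kept (default 0.01).
#' @param max_intron_offset Maximum distance into the intron kept, bases
#'   (default 20).
#' @param splice_loss_offset Maximum intronic distance at which a
#'   splice-region variant counts as a splice-site loss, bases (default 2).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_quality = 50, min_vaf_pct = 3,
                          max_pop_af = 0.01, max_intron_offset = 20,
                          splice_loss_offset = 2) {
  cfg <- list(min_call_quality = min_call_quality, min_vaf_pct = min_vaf_pct,
              max_pop_af = max_pop_af, max_intron_offset = max_intron_offset,
              splice_loss_offset = splice_loss_offset)
  if (any(unlist(cfg) < 0)) stop("filter thresholds must be >= 0")
  if (min_vaf_pct > 100) stop("min_vaf_pct must be <= 100")
  structure(cfg, class = "filter_config")
}

#' Read a filter configuration from JSON
#'
#' Keys present in the file override the defaults of [filter_config()].
#'
#' @param path JSON object file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filter_config, user)
}

filter_result <- function(variants, keep, reason) {
  removed <- variants[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = variants[keep, , drop = FALSE], removed = removed)
}

#' Confidence filter (cascade stage 1)
#'
#' Keeps a variant iff its call quality is at least `min_call_quality`, its
#' VAF is at least `min_vaf_pct`, and it does not fall into an excluded
#' exonically-variable window. Removals are tagged with the first failing
#' criterion in the order quality, vaf, window.
#'
#' @param variants Variant data frame (normalized).
#' @param config A [filter_config()].
#' @param windows Exclusion windows from [read_window_bed()].
#' @return List with `kept` and `removed` (removed carries a `reason` column).
#' @export
confidence_filter <- function(variants, config = filter_config(),
                              windows = NULL) {
  if (nrow(variants) == 0L)
    return(filter_result(variants, logical(0), character(0)))
  if (is.null(windows))
    windows <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  fail_q <- variants$call_quality < config$min_call_quality
  fail_v <- variants$vaf < config$min_vaf_pct
  fail_w <- window_contains(windows, variants$chrom, variants$pos)
  reason <- ifelse(fail_q, "quality", ifelse(fail_v, "vaf",
              ifelse(fail_w, "window", NA_character_)))
  filter_result(variants, !(fail_q | fail_v | fail_w), reason)
}

#' Common-variant filter (cascade stage 2)
#'
#' Removes variants with a population allele fraction above `max_pop_af`
#' (prevalence > 1% in the normal population by default) unless they are
#' established pathogenic variants. A missing population allele fraction
#' means the variant is absent from the population databases and is kept.
#'
#' @inheritParams confidence_filter
#' @return List with `kept` and `removed`.
#' @export
common_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0L)
    return(filter_result(variants, logical(0), character(0)))
  pa <- variants$pop_af
  common <- !is.na(pa) & pa > config$max_pop_af
  keep <- !common | variants$established_pathogenic
  filter_result(variants, keep, ifelse(keep, NA_character_, "common"))
}

#' Predicted-deleterious filter (cascade stage 3)
#'
#' Keeps a variant iff it lies no more than `max_intron_offset` bases into
#' the intron AND at least one retention clause holds: ACMG class pathogenic,
#' likely pathogenic or VUS; gain- or loss-of-function association; an effect
#' among frameshift, in-frame indel, start/stop codon change, missense or
#' copy number loss; a splice-region variant within `splice_loss_offset`
#' bases of the exon (splice-site loss); or an external splice-disruption
#' prediction. Removals are tagged "intron_offset" or "not_deleterious".
#'
#' @inheritParams confidence_filter
#' @param classes Optional character vector of ACMG classes aligned with the
#'   rows; computed with [acmg_classify()] from the evidence codes when NULL,
#'   so the same classification engine drives filtering and reporting.
#' @return List with `kept` and `removed`.
#' @export
deleterious_filter <- function(variants, config = filter_config(),
                               classes = NULL) {
  if (nrow(variants) == 0L)
    return(filter_result(variants, logical(0), character(0)))
  if (is.null(classes))
    classes <- vapply(variants$evidence_codes, acmg_classify, character(1),
                      USE.NAMES = FALSE)
  off <- abs(variants$intron_offset)
  fail_off <- off > config$max_intron_offset
  lof_effects <- c("frameshift", "inframe_indel", "start_loss",
                   "stop_change", "missense", "copy_number_loss")
  retain <- classes %in% c("pathogenic", "likely_pathogenic", "VUS") |
    variants$gof_flag | variants$lof_flag |
    variants$effect %in% lof_effects |
    (variants$effect == "splice_region" & off <= config$splice_loss_offset) |
    variants$splice_pred_flag
  keep <- !fail_off & retain
  reason <- ifelse(fail_off, "intron_offset",
                   ifelse(retain, NA_character_, "not_deleterious"))
  filter_result(variants, keep, reason)
}

#' Run the sequential three-filter cascade on one sample
#'
#' Applies the confidence, common-variant and predicted-deleterious filters
#' in order and reports per-stage attrition.
#'
#' @inheritParams confidence_filter
#' @param sample_id Label used in the report (defaults to the variants'
#'   sample_id when present).
#' @return List with `kept` (survivors), `removed` (all removed rows with
#'   `stage` and `reason` columns) and `report` (data frame: sample, stage,
#'   n_in, n_removed, n_out plus one column per removal reason).
#' @export
run_cascade <- function(variants, config = filter_config(), windows = NULL,
                        sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(variants) > 0L && !is.na(variants$sample_id[1]))
      variants$sample_id[1] else "sample"

  s1 <- confidence_filter(variants, config, windows)
  s2 <- common_filter(s1$kept, config)
  s3 <- deleterious_filter(s2$kept, config)

  stages <- list(confidence = s1, common = s2, deleterious = s3)
  ins <- c(nrow(variants), nrow(s1$kept), nrow(s2$kept))
  removed <- mapply(function(st, name) {
    r <- st$removed
    if (nrow(r) > 0L) r$stage <- name
    r
  }, stages, names(stages), SIMPLIFY = FALSE)
  removed_all <- do.call(rbind, removed[vapply(removed, nrow, integer(1)) > 0])
  if (is.null(removed_all)) {
    removed_all <- variants[0, , drop = FALSE]
    removed_all$reason <- character(0)
    removed_all$stage <- character(0)
  }
  rownames(removed_all) <- NULL

  reasons <- c("quality", "vaf", "window", "common", "intron_offset",
               "not_deleterious")
  report <- data.frame(
    sample = sample_id, stage = names(stages), n_in = ins,
    n_removed = vapply(stages, function(s) nrow(s$removed), integer(1)),
    n_out = vapply(stages, function(s) nrow(s$kept), integer(1)),
    stringsAsFactors = FALSE
  )
  for (r in reasons)
    report[[r]] <- vapply(stages, function(s)
      sum(s$removed$reason == r), integer(1))
  rownames(report) <- NULL

  stopifnot(report$n_in - report$n_removed == report$n_out,
            all(diff(report$n_out) <= 0) || nrow(variants) == 0L)
  list(kept = s3$kept, removed = removed_all, report = report)
}
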