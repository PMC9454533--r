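read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("ingest: manifest not found: ", manifest)
    dir <- dirname(manifest)
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    for (col in c("plasma_vcf", "urine_vcf")) {
      rel <- !file.exists(manifest[[col]])
      manifest[[col]][rel] <- file.path(dir, manifest[[col]][rel])
    }
  }
  need <- c("patient_id", "plasma_vcf", "urine_vcf")
  if (!all(need %in% names(manifest)))
    stop("ingest: manifest needs columns ", paste(need, collapse = ", "))
  manifest$patient_id <- as.character(manifest$patient_id)
  manifest
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end matched-cohort pipeline
#'
#' Ingest -> filter cascade -> classification -> concordance -> cohort
#' statistics -> reports. For every sample the annotated VCF is read and
#' normalized, the three-stage cascade applied, and the survivors classified
#' (ACMG class, tier, VAF bin) and written back as an annotated VCF. Matched
#' pairs are intersected by variant key, the cohort summarized, and the
#' concentration statistics (Spearman, Wilcoxon signed-rank) plus the
#' class-by-fluid chi-square computed. All report tables are written as TSV
#' under `outdir` together with `stats.json` and `summary.json`; numbers in
#' the JSON files are stored unrounded.
#'
#' Errors are attributed to the failing stage. Output is deterministic:
#' identical inputs give identical `summary.json`.
#'
#' @param manifest Path to a TSV (patient_id, plasma_vcf, urine_vcf; relative
#'   VCF paths are resolved against the manifest's directory) or an
#'   equivalent data frame.
#' @param concentrations Path to the cfDNA concentration CSV, or NULL to skip
#'   concentration statistics.
#' @param windows Path to the exclusion-window BED, or NULL for no window
#'   exclusions.
#' @param config A [filter_config()].
#' @param tag_config Tag configuration for VCF ingestion.
#' @param outdir Output directory, or NULL to skip writing files.
#' @return Invisibly, a list: `summary` (cohort summary), `survivors`
#'   (pooled classified table), `cascade_report`, `pairs`, `stats`,
#'   `summary_json` (the unrounded headline numbers).
#' @export
run_pipeline <- function(manifest, concentrations = NULL, windows = NULL,
                         config = filter_config(),
                         tag_config = default_tag_config(), outdir = NULL) {
  manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0L) stop("ingest: empty manifest")
  win <- if (is.null(windows))
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  else read_window_bed(windows)
  conc <- if (is.null(concentrations)) NULL
          else read_concentrations(concentrations)

  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  survivors <- list()
  reports <- list()
  pairs <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    per_fluid <- list()
    for (fluid in FLUIDS) {
      path <- manifest[[paste0(fluid, "_vcf")]][i]
      if (!file.exists(path))
        stop("ingest: missing VCF for patient ", pid, " (", fluid, "): ",
             path)
      v <- tryCatch(
        read_sample_vcf(path, tag_config, sample_id = pid, fluid = fluid),
        error = function(e) stop("ingest: patient ", pid, " (", fluid, "): ",
                                 conditionMessage(e)))
      res <- tryCatch(
        run_cascade(v, config, win, sample_id = paste(pid, fluid, sep = "_")),
        error = function(e) stop("cascade: patient ", pid, " (", fluid, "): ",
                                 conditionMessage(e)))
      kept <- classify_variants(res$kept)
      per_fluid[[fluid]] <- kept
      survivors[[paste(pid, fluid)]] <- kept
      reports[[paste(pid, fluid)]] <- res$report
      if (!is.null(outdir))
        write_sample_vcf(kept,
                         file.path(outdir, paste0(pid, "_", fluid,
                                                  "_filtered.vcf")),
                         sample_name = paste(pid, fluid, sep = "_"),
                         extra_info = list(
                           ACMG_CLASS = kept$acmg_class,
                           TIER = kept$tier,
                           VAFBIN = as.character(kept$vaf_bin)))
    }
    pairs[[pid]] <- tryCatch(
      match_pair(per_fluid$plasma, per_fluid$urine, patient_id = pid),
      error = function(e) stop("concordance: patient ", pid, ": ",
                               conditionMessage(e)))
  }

  pooled <- do.call(rbind, survivors)
  rownames(pooled) <- NULL
  cascade_report <- do.call(rbind, reports)
  rownames(cascade_report) <- NULL
  summary <- cohort_summarize(pairs, pooled)

  stats <- list()
  if (!is.null(conc) && nrow(conc) >= 3L) {
    stats$conc_spearman <- tryCatch(
      spearman_rho(conc$plasma_ng_ml, conc$urine_ng_ml),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               method = conditionMessage(e)))
    stats$conc_wilcoxon <- tryCatch(
      wilcoxon_signed_rank(conc$plasma_ng_ml, conc$urine_ng_ml),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               method = conditionMessage(e)))
    stats$conc_plasma <- median_range(conc$plasma_ng_ml)
    stats$conc_urine <- median_range(conc$urine_ng_ml)
  }
  class_mat <- t(as.matrix(summary$class_dist[, c("plasma", "urine")]))
  colnames(class_mat) <- summary$class_dist$class
  class_mat <- class_mat[, colSums(class_mat) > 0, drop = FALSE]
  stats$class_chisq <- if (ncol(class_mat) >= 2L)
    chi_square_independence(class_mat)
  else list(statistic = NA_real_, p_value = NA_real_,
            method = "fewer than two populated classes")

  summary_json <- list(
    n_patients = nrow(manifest),
    plasma_total = summary$venn$plasma_total,
    urine_total = summary$venn$urine_total,
    grand_total = summary$venn$grand_total,
    shared = summary$venn$shared,
    plasma_exclusive = summary$venn$plasma_exclusive,
    urine_exclusive = summary$venn$urine_exclusive,
    median_plasma_per_sample = summary$medians$plasma_per_sample,
    median_urine_per_sample = summary$medians$urine_per_sample,
    median_shared_per_sample = summary$medians$shared_per_sample,
    median_recovery_pu_pct = summary$medians$recovery_pu,
    median_recovery_up_pct = summary$medians$recovery_up,
    median_path_recovery_pu_pct = summary$medians$path_recovery_pu,
    median_path_recovery_up_pct = summary$medians$path_recovery_up
  )

  if (!is.null(outdir)) {
    write_tsv(cascade_report, file.path(outdir, "cascade_report.tsv"))
    venn_df <- data.frame(set = c("plasma_exclusive", "shared",
                                  "urine_exclusive", "plasma_total",
                                  "urine_total", "grand_total"),
                          count = c(summary$venn$plasma_exclusive,
                                    summary$venn$shared,
                                    summary$venn$urine_exclusive,
                                    summary$venn$plasma_total,
                                    summary$venn$urine_total,
                                    summary$venn$grand_total))
    write_tsv(venn_df, file.path(outdir, "venn.tsv"))
    write_tsv(summary$per_sample, file.path(outdir, "per_sample_counts.tsv"))
    write_tsv(summary$per_sample[, c("patient_id", "recovery_pu",
                                     "recovery_up", "path_recovery_pu",
                                     "path_recovery_up")],
              file.path(outdir, "recovery.tsv"))
    write_tsv(summary$vaf_bins, file.path(outdir, "vaf_bins.tsv"))
    write_tsv(summary$class_dist, file.path(outdir, "class_dist.tsv"))
    write_tsv(summary$tier_dist, file.path(outdir, "tier_dist.tsv"))
    write_tsv(summary$gene_table, file.path(outdir, "gene_table.tsv"))
    pm <- summary$pathogenic_matrix
    pm_df <- data.frame(variant = rownames(pm), pm, check.names = FALSE)
    write_tsv(pm_df, file.path(outdir, "pathogenic_matrix.tsv"))
    jsonlite::write_json(stats, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(summary = summary, survivors = pooled,
                 cascade_report = cascade_report, pairs = pairs,
                 stats = stats, summary_json = summary_json))
}
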