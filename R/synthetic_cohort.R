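#' Bundled breast-cancer gene panel (synthetic coordinates)
#'
#' 93 breast-cancer-associated gene symbols mirroring the scale of a
#' commercial targeted panel. Chromosome assignments and coordinates are
#' synthetic placeholders used by the cohort generator; only the symbol set
#' and its size are meaningful.
#'
#' @return Data frame with columns gene, chrom, start, end.
#' @export
panel_genes <- function() {
  utils::read.table(system.file("extdata", "breast_panel_genes.tsv",
                                package = "ctdnaconcord", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "integer"))
}

#' Synthetic matched-cohort configuration
#'
#' Defines the statistical structure of a generated plasma/urine cohort.
#' The defaults emulate the study conditions: per-sample survivor counts
#' log-normal around medians 66 (plasma) and 110 (urine); a VAF mixture
#' putting masses 37/32/19/10/2 percent on the abundance bins 3-5, 5-10,
#' 10-20, 20-50 and 50-100; class proportions dominated by VUS (85%) with
#' 5% pathogenic and 9% likely pathogenic; a 0.47 probability that a plasma
#' survivor's key is also planted in urine (the observed ~47% plasma-in-urine
#' recovery); and log-normal cfDNA concentrations with medians 172 (plasma)
#' and 196 (urine) ng/mL coupled through a Gaussian copula with correlation
#' -0.19, urine zero-inflated at 2/15 (undetectable cfDNA).
#'
#' Planted removals are expressed as rates relative to the number of
#' survivors, one rate per cascade removal reason.
#'
#' @param n_patients Number of matched pairs.
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param plasma_median_count,urine_median_count Median per-sample survivor
#'   counts.
#' @param count_sdlog Log-scale SD of the per-sample survivor counts.
#' @param shared_fraction Probability a plasma survivor is shared with urine.
#' @param vaf_bin_masses Probabilities of the five VAF bins (renormalized).
#' @param class_props Named proportions of the five ACMG classes
#'   (renormalized).
#' @param removal_rates Named planted-removal rates per reason
#'   (quality, vaf, window, common, intron_offset, not_deleterious).
#' @param plasma_conc_median,urine_conc_median,plasma_conc_sdlog,
#'   urine_conc_sdlog Log-normal concentration parameters, ng/mL.
#' @param urine_zero_prob Probability a urine concentration is 0.
#' @param conc_correlation Gaussian-copula correlation between the fluids'
#'   concentrations.
#' @param gene_weights Optional named sampling weights over the panel genes
#'   (e.g. to emulate the large-gene bias of MUC16); uniform when NULL.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 15, seed,
                             plasma_median_count = 66,
                             urine_median_count = 110,
                             count_sdlog = 0.45,
                             shared_fraction = 0.47,
                             vaf_bin_masses = c(0.37, 0.32, 0.19, 0.10, 0.02),
                             class_props = c(pathogenic = 0.05,
                                             likely_pathogenic = 0.09,
                                             VUS = 0.85,
                                             likely_benign = 0.007,
                                             benign = 0.003),
                             removal_rates = c(quality = 0.08, vaf = 0.08,
                                               window = 0.03, common = 0.05,
                                               intron_offset = 0.03,
                                               not_deleterious = 0.03),
                             plasma_conc_median = 172,
                             urine_conc_median = 196,
                             plasma_conc_sdlog = 0.6,
                             urine_conc_sdlog = 1.1,
                             urine_zero_prob = 2 / 15,
                             conc_correlation = -0.19,
                             gene_weights = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_patients >= 0, length(vaf_bin_masses) == 5,
            all(vaf_bin_masses >= 0), sum(vaf_bin_masses) > 0,
            setequal(names(class_props), ACMG_CLASSES),
            all(class_props >= 0), sum(class_props) > 0,
            all(removal_rates >= 0),
            shared_fraction >= 0, shared_fraction <= 1,
            urine_zero_prob >= 0, urine_zero_prob <= 1,
            abs(conc_correlation) <= 1)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    plasma_median_count = plasma_median_count,
    urine_median_count = urine_median_count, count_sdlog = count_sdlog,
    shared_fraction = shared_fraction,
    vaf_bin_masses = vaf_bin_masses / sum(vaf_bin_masses),
    class_props = class_props[ACMG_CLASSES] / sum(class_props),
    removal_rates = removal_rates,
    plasma_conc_median = plasma_conc_median,
    urine_conc_median = urine_conc_median,
    plasma_conc_sdlog = plasma_conc_sdlog,
    urine_conc_sdlog = urine_conc_sdlog,
    urine_zero_prob = urine_zero_prob,
    conc_correlation = conc_correlation,
    gene_weights = gene_weights
  ), class = "synthetic_config")
}

# Deterministic per-patient substream seed, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 + i * 7919) %%
    2147483647L
}

#' Draw VAF percentages from the configured bin mixture
#'
#' Draws a bin by the configured masses, then uniformly within the bin;
#' results lie in \[3, 100\].
#'
#' @param n Number of draws.
#' @param masses Probabilities of the five bins (renormalized).
#' @return Numeric vector of VAF percentages.
#' @export
sample_vaf <- function(n, masses = c(0.37, 0.32, 0.19, 0.10, 0.02)) {
  stopifnot(length(masses) == 5, all(masses >= 0), sum(masses) > 0)
  masses <- masses / sum(masses)
  bin <- sample.int(5L, n, replace = TRUE, prob = masses)
  lo <- VAF_BIN_BREAKS[bin]
  hi <- VAF_BIN_BREAKS[bin + 1L]
  stats::runif(n, lo, hi)
}

EVIDENCE_TEMPLATES <- list(
  pathogenic = c("PVS1,PS1", "PS1,PS2", "PVS1,PM1,PM2", "PS1,PM1,PM2,PM3"),
  likely_pathogenic = c("PVS1,PM1", "PS1,PM1", "PM1,PM2,PM3",
                        "PS1,PP1,PP2", "PM1,PM2,PP1,PP2"),
  VUS = c("", "PM1", "PP1", "PS1", "PM1,PP1"),
  likely_benign = c("BS1,BP1", "BP1,BP2"),
  benign = c("BA1", "BS1,BS2")
)

draw_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  del <- stats::runif(n) < 0.05   # a few deletions; leading base differs
  ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1L, 1L)
  swap <- del & substr(ref, 1L, 1L) == alt & nchar(alt) == 1L &
    substr(ref, 2L, 2L) == substr(ref, 1L, 1L)
  # avoid ref like "AA" with alt "A" needing context left-alignment:
  ref[swap] <- paste0(substr(ref[swap], 1L, 1L),
                      ifelse(substr(ref[swap], 1L, 1L) == "A", "C", "A"))
  list(ref = ref, alt = alt)
}

# records are built as plain lists and assembled column-wise at the end;
# per-record data.frame construction is far too slow at cohort scale
blank_record <- function(pid, fluid) {
  list(
    chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
    alt = NA_character_, gene = NA_character_, call_quality = NA_real_,
    vaf = NA_real_, depth = NA_integer_, pop_af = NA_real_,
    effect = "missense", intron_offset = 0L, splice_pred_flag = FALSE,
    gof_flag = FALSE, lof_flag = FALSE, evidence_codes = "",
    clinical_evidence_level = "none", established_pathogenic = FALSE,
    sample_id = pid, fluid = fluid, key = NA_character_
  )
}

records_to_frame <- function(recs) {
  proto <- blank_record("", "")
  cols <- lapply(names(proto), function(nm) {
    template <- proto[[nm]]
    vapply(recs, function(r) as.vector(r[[nm]]), template)
  })
  names(cols) <- names(proto)
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

place_variant <- function(rec, panel, windows, used_keys, in_window = FALSE,
                          gene_weights = NULL) {
  repeat {
    g <- if (is.null(gene_weights)) sample.int(nrow(panel), 1L)
         else sample.int(nrow(panel), 1L, prob = gene_weights)
    row <- panel[g, ]
    if (in_window) {
      w <- windows[windows$chrom == row$chrom &
                     windows$start >= row$start & windows$end <= row$end, ]
      if (nrow(w) == 0L) next
      wi <- w[sample.int(nrow(w), 1L), ]
      pos <- sample((wi$start + 1L):wi$end, 1L)
    } else {
      pos <- sample((row$start + 1000L):row$end, 1L)
      if (any(window_contains(windows, row$chrom, pos))) next
    }
    al <- draw_alleles(1L)
    key <- variant_key(row$chrom, pos, al$ref, al$alt)
    if (!(key %in% used_keys)) {
      rec$chrom <- row$chrom; rec$pos <- pos
      rec$ref <- al$ref; rec$alt <- al$alt
      rec$gene <- row$gene; rec$key <- key
      return(rec)
    }
  }
}

survivor_attributes <- function(rec, cfg) {
  cls <- sample(ACMG_CLASSES, 1L, prob = cfg$class_props)
  templates <- EVIDENCE_TEMPLATES[[cls]]
  rec$evidence_codes <- sample(templates, 1L)
  rec$vaf <- sample_vaf(1L, cfg$vaf_bin_masses)
  rec$call_quality <- stats::runif(1, 50, 250)
  rec$depth <- as.integer(round(stats::runif(1, 200, 2000)))
  rec$pop_af <- if (stats::runif(1) < 0.75) stats::runif(1, 0, 0.01)
                else NA_real_
  if (cls %in% c("benign", "likely_benign")) {
    rec$effect <- "missense"   # retained by effect despite benign class
  } else {
    eff <- sample(c("missense", "frameshift", "inframe_indel", "stop_change",
                    "start_loss", "synonymous", "splice_region", "intronic"),
                  1L, prob = c(0.55, 0.05, 0.03, 0.04, 0.01, 0.08, 0.06, 0.18))
    rec$effect <- eff
    if (eff == "splice_region") {
      rec$intron_offset <- sample(1:20, 1L)
      rec$splice_pred_flag <- stats::runif(1) < 0.5
    } else if (eff == "intronic") {
      rec$intron_offset <- sample(3:20, 1L)
    }
  }
  if (cls %in% c("pathogenic", "likely_pathogenic")) {
    rec$lof_flag <- stats::runif(1) < 0.3
    rec$gof_flag <- stats::runif(1) < 0.05
    rec$clinical_evidence_level <- sample(
      c("A", "B", "C", "D", "none"), 1L,
      prob = c(0.02, 0.02, 0.30, 0.30, 0.36))
    if (cls == "pathogenic" && stats::runif(1) < 0.02) {
      rec$pop_af <- stats::runif(1, 0.011, 0.3)   # rescued common variant
      rec$established_pathogenic <- TRUE
    }
  }
  rec$class_label <- cls
  rec
}

removal_attributes <- function(rec, reason, cfg) {
  # base: would survive every stage, then violate exactly one criterion
  rec$vaf <- sample_vaf(1L, cfg$vaf_bin_masses)
  rec$call_quality <- stats::runif(1, 50, 250)
  rec$depth <- as.integer(round(stats::runif(1, 200, 2000)))
  rec$pop_af <- stats::runif(1, 0, 0.01)
  rec$effect <- "missense"
  rec$class_label <- "VUS"
  switch(reason,
    quality = { rec$call_quality <- stats::runif(1, 5, 49.9) },
    vaf = { rec$vaf <- stats::runif(1, 0.1, 2.9) },
    window = { },   # placement inside a window is done by the caller
    common = { rec$pop_af <- stats::runif(1, 0.011, 0.5) },
    intron_offset = {
      rec$effect <- "intronic"
      rec$intron_offset <- sample(21:200, 1L)
    },
    not_deleterious = {
      rec$effect <- "synonymous"
      rec$evidence_codes <- "BS1,BS2"
      rec$class_label <- "benign"
    },
    stop("unknown removal reason: ", reason)
  )
  rec
}

generate_sample <- function(pid, fluid, n_survivors, cfg, panel, windows,
                            shared_pool = NULL) {
  used <- character(0)
  recs <- list()
  truth <- list()
  add <- function(rec, fate, shared) {
    used <<- c(used, rec$key)
    cls <- rec$class_label
    rec$class_label <- NULL
    recs[[length(recs) + 1L]] <<- rec
    truth[[length(truth) + 1L]] <<- list(
      patient_id = pid, fluid = fluid, key = rec$key, gene = rec$gene,
      fate = fate, class_label = cls, shared = shared)
  }

  shared_flags <- logical(0)
  if (is.null(shared_pool)) {          # plasma: draw fresh survivors
    shared_flags <- stats::runif(n_survivors) < cfg$shared_fraction
    for (i in seq_len(n_survivors)) {
      rec <- place_variant(blank_record(pid, fluid), panel, windows, used,
                           gene_weights = cfg$gene_weights)
      rec <- survivor_attributes(rec, cfg)
      add(rec, "survive", shared_flags[i])
    }
  } else {                             # urine: replay shared keys first
    for (i in seq_len(nrow(shared_pool))) {
      rec <- blank_record(pid, fluid)
      for (col in c("chrom", "pos", "ref", "alt", "gene", "key", "effect",
                    "intron_offset", "evidence_codes",
                    "clinical_evidence_level", "splice_pred_flag",
                    "gof_flag", "lof_flag", "established_pathogenic",
                    "pop_af"))
        rec[[col]] <- shared_pool[[col]][i]
      rec$vaf <- sample_vaf(1L, cfg$vaf_bin_masses)
      rec$call_quality <- stats::runif(1, 50, 250)
      rec$depth <- as.integer(round(stats::runif(1, 200, 2000)))
      rec$class_label <- shared_pool$class_label[i]
      add(rec, "survive", TRUE)
    }
    n_new <- max(0L, n_survivors - nrow(shared_pool))
    for (i in seq_len(n_new)) {
      rec <- place_variant(blank_record(pid, fluid), panel, windows, used,
                           gene_weights = cfg$gene_weights)
      rec <- survivor_attributes(rec, cfg)
      add(rec, "survive", FALSE)
    }
  }

  n_surv <- length(recs)
  for (reason in names(cfg$removal_rates)) {
    k <- round(cfg$removal_rates[[reason]] * n_surv)
    if (k > 0 && reason == "window" && nrow(windows) == 0L)
      stop("infeasible plant: windowed removal requested with empty window set")
    for (i in seq_len(k)) {
      rec <- place_variant(blank_record(pid, fluid), panel, windows, used,
                           in_window = (reason == "window"),
                           gene_weights = cfg$gene_weights)
      rec <- removal_attributes(rec, reason, cfg)
      stage <- switch(reason, quality = , vaf = , window = "confidence",
                      common = "common", "deleterious")
      add(rec, paste(stage, reason, sep = ":"), FALSE)
    }
  }

  variants <- records_to_frame(recs)
  truth <- data.frame(
    patient_id = vapply(truth, `[[`, character(1), "patient_id"),
    fluid = vapply(truth, `[[`, character(1), "fluid"),
    key = vapply(truth, `[[`, character(1), "key"),
    gene = vapply(truth, `[[`, character(1), "gene"),
    fate = vapply(truth, `[[`, character(1), "fate"),
    class_label = vapply(truth, `[[`, character(1), "class_label"),
    shared = vapply(truth, `[[`, logical(1), "shared"),
    stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, truth = truth,
       shared_records = if (is.null(shared_pool)) {
         out <- variants
         out$class_label <- truth$class_label
         out[truth$fate == "survive" & truth$shared, , drop = FALSE]
       } else NULL)
}

#' Generate a synthetic matched plasma/urine cohort on disk
#'
#' Emits, for each patient, one plasma and one urine annotated VCF in the
#' pipeline's tag dialect, plus a shared exclusion-window BED, a cfDNA
#' concentration CSV, a sample manifest TSV and a ground-truth table giving
#' every record's intended cascade fate, class label and shared status.
#' Output is byte-identical for identical (config, seed): one cohort-level
#' stream seeds window placement and concentrations, and each patient uses a
#' substream derived from (seed, patient index).
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `manifest` (patient_id, plasma_vcf, urine_vcf; absolute
#'   paths), `truth`, `concentrations`, `paths` (windows_bed,
#'   concentrations_csv, truth_tsv, manifest_tsv) and the config, invisibly.
#' @export
generate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  panel <- panel_genes()
  if (!is.null(config$gene_weights))
    stopifnot(length(config$gene_weights) == nrow(panel))

  set.seed(config$seed)
  # cohort-level exclusion windows: 100-base windows in 8 panel genes
  widx <- sample.int(nrow(panel), 8L)
  windows <- data.frame(chrom = panel$chrom[widx],
                        start = panel$start[widx] + 100L,
                        end = panel$start[widx] + 200L,
                        stringsAsFactors = FALSE)
  windows <- windows[order(windows$chrom, windows$start), ]
  rownames(windows) <- NULL

  n <- config$n_patients
  z1 <- stats::rnorm(n)
  z2 <- config$conc_correlation * z1 +
    sqrt(1 - config$conc_correlation^2) * stats::rnorm(n)
  plasma_conc <- round(stats::qlnorm(stats::pnorm(z1),
                                     log(config$plasma_conc_median),
                                     config$plasma_conc_sdlog))
  urine_conc <- round(stats::qlnorm(stats::pnorm(z2),
                                    log(config$urine_conc_median),
                                    config$urine_conc_sdlog))
  urine_conc[stats::runif(n) < config$urine_zero_prob] <- 0

  manifest <- data.frame(patient_id = character(0), plasma_vcf = character(0),
                         urine_vcf = character(0), stringsAsFactors = FALSE)
  truth_all <- list()
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    pid <- sprintf("P%02d", i)
    n_plasma <- max(5L, round(stats::rlnorm(1, log(config$plasma_median_count),
                                            config$count_sdlog)))
    n_urine <- max(5L, round(stats::rlnorm(1, log(config$urine_median_count),
                                           config$count_sdlog)))
    plasma <- generate_sample(pid, "plasma", n_plasma, config, panel, windows)
    urine <- generate_sample(pid, "urine", n_urine, config, panel, windows,
                             shared_pool = plasma$shared_records)
    p_path <- file.path(outdir, paste0(pid, "_plasma.vcf"))
    u_path <- file.path(outdir, paste0(pid, "_urine.vcf"))
    write_sample_vcf(plasma$variants, p_path, paste0(pid, "_plasma"))
    write_sample_vcf(urine$variants, u_path, paste0(pid, "_urine"))
    manifest <- rbind(manifest, data.frame(
      patient_id = pid, plasma_vcf = normalizePath(p_path),
      urine_vcf = normalizePath(u_path), stringsAsFactors = FALSE))
    truth_all[[i]] <- rbind(plasma$truth, urine$truth)
  }
  truth <- if (length(truth_all)) do.call(rbind, truth_all) else
    data.frame(patient_id = character(0), fluid = character(0),
               key = character(0), gene = character(0), fate = character(0),
               class_label = character(0), shared = logical(0),
               stringsAsFactors = FALSE)

  conc <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                     plasma_ng_ml = plasma_conc, urine_ng_ml = urine_conc,
                     stringsAsFactors = FALSE)

  paths <- list(windows_bed = file.path(outdir, "windows.bed"),
                concentrations_csv = file.path(outdir, "concentrations.csv"),
                truth_tsv = file.path(outdir, "truth.tsv"),
                manifest_tsv = file.path(outdir, "manifest.tsv"))
  writeLines(sprintf("%s\t%d\t%d", windows$chrom, windows$start, windows$end),
             paths$windows_bed)
  utils::write.table(conc, paths$concentrations_csv, sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # manifest on disk uses basenames so identical (config, seed) give
  # byte-identical trees wherever they are generated; run_pipeline resolves
  # relative paths against the manifest's directory
  manifest_rel <- manifest
  manifest_rel$plasma_vcf <- basename(manifest_rel$plasma_vcf)
  manifest_rel$urine_vcf <- basename(manifest_rel$urine_vcf)
  utils::write.table(manifest_rel, paths$manifest_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, truth = truth, concentrations = conc,
                 windows = windows, paths = paths, config = config))
}
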