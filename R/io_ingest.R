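#' @importFrom vcfR read.vcfR getFIX extract.info extract.gt
#' @importFrom utils read.csv read.table write.table
NULL

# Legal evidence-code alphabet (ACMG/AMP 2015).
ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

EFFECT_LEVELS <- c("frameshift", "inframe_indel", "start_loss", "stop_change",
                   "missense", "synonymous", "splice_region", "intronic",
                   "copy_number_loss", "other")

EVIDENCE_LEVELS <- c("A", "B", "C", "D", "none")

FLUIDS <- c("plasma", "urine")

#' Default annotation tag configuration
#'
#' Names the VCF INFO/FORMAT tags that carry each annotation consumed by the
#' pipeline. `call_quality = "QUAL"` means the site QUAL column; any other
#' value is taken as an INFO tag name. Boolean annotations are encoded as
#' Integer 0/1 tags. `vaf` is the variant allele fraction in percent; when the
#' tag is absent the reader falls back to 100 * AD(alt)/DP.
#'
#' @return Named list of tag names.
#' @export
default_tag_config <- function() {
  list(
    call_quality = "QUAL",
    gene = "GENE",
    vaf = "VAFPCT",
    pop_af = "POPAF",
    effect = "EFFECT",
    intron_offset = "INTOFF",
    splice_pred = "SPLICEPRED",
    gof = "GOF",
    lof = "LOF",
    evidence = "EVID",
    clinical_evidence = "CLINEVID",
    established_pathogenic = "ESTPATH"
  )
}

#' Read a tag configuration from a JSON file
#'
#' Keys present in the file override the defaults of [default_tag_config()].
#'
#' @param path Path to a JSON object file.
#' @return Named list of tag names.
#' @export
read_tag_config <- function(path) {
  cfg <- default_tag_config()
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown tag_config keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Empty annotated-variant table
#'
#' The column schema used for every variant table in the package: one row per
#' called ALT allele, identified by the normalized (chrom, pos, ref, alt) key.
#'
#' @return Zero-row data frame with the annotated-variant columns.
#' @export
empty_variants <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), call_quality = numeric(0),
    vaf = numeric(0), depth = integer(0), pop_af = numeric(0),
    effect = character(0), intron_offset = integer(0),
    splice_pred_flag = logical(0), gof_flag = logical(0),
    lof_flag = logical(0), evidence_codes = character(0),
    clinical_evidence_level = character(0),
    established_pathogenic = logical(0),
    sample_id = character(0), fluid = character(0), key = character(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a variant table against the domain invariants
#'
#' Checks positions, alleles, VAF range, population AF range, the effect and
#' fluid vocabularies and the evidence-code alphabet; stops on the first
#' violation.
#'
#' @param variants Variant data frame.
#' @return The input, invisibly.
#' @export
validate_variants <- function(variants) {
  if (nrow(variants) == 0L) return(invisible(variants))
  stopifnot(is.numeric(variants$pos), is.numeric(variants$vaf))
  if (any(variants$pos < 1L)) stop("invalid variant: pos must be >= 1")
  ok_allele <- function(a) grepl("^[ACGT]+$", a)
  if (!all(ok_allele(variants$ref)) || !all(ok_allele(variants$alt)))
    stop("invalid variant: alleles must be non-empty over A,C,G,T")
  if (any(variants$ref == variants$alt)) stop("invalid variant: ref == alt")
  if (any(variants$vaf < 0 | variants$vaf > 100))
    stop("invalid variant: vaf outside [0, 100]")
  pa <- variants$pop_af
  if (any(!is.na(pa) & (pa < 0 | pa > 1)))
    stop("invalid variant: pop_af outside [0, 1]")
  if (!all(variants$effect %in% EFFECT_LEVELS))
    stop("invalid variant: unknown effect value")
  if (!all(variants$fluid %in% c(FLUIDS, NA)))
    stop("invalid variant: fluid must be plasma or urine")
  if (!all(variants$clinical_evidence_level %in% EVIDENCE_LEVELS))
    stop("invalid variant: unknown clinical evidence level")
  codes <- unlist(strsplit(variants$evidence_codes[variants$evidence_codes != ""],
                           ",", fixed = TRUE))
  bad <- setdiff(trimws(codes), ACMG_CODES)
  if (length(bad))
    stop("malformed evidence code(s): ", paste(unique(bad), collapse = ", "))
  invisible(variants)
}

info_or_default <- function(vcf, tag, default, numeric = FALSE) {
  x <- suppressWarnings(vcfR::extract.info(vcf, element = tag,
                                           as.numeric = numeric))
  if (is.null(x)) x <- rep(NA, nrow(vcf@fix))
  x[is.na(x)] <- default
  x
}

#' Read one sample's annotated VCF into a variant table
#'
#' Reads a VCF v4.2 file, splits multi-allelic records into one row per ALT
#' allele (per-allele annotation tags are split positionally), normalizes each
#' row with [normalize_variant()] and validates the result. Call quality comes
#' from the QUAL column unless `tag_config$call_quality` names an INFO tag.
#' VAF (percent) comes from the configured tag and falls back to
#' 100 * AD(alt)/DP; a record with neither is an error. Missing optional
#' annotations take documented defaults: pop_af NA (kept by the common-variant
#' filter), effect "other", intron offset 0, flags FALSE, evidence codes empty
#' (classifies as VUS), clinical evidence level "none".
#'
#' @param path VCF file path.
#' @param tag_config Tag configuration, see [default_tag_config()].
#' @param sample_id,fluid Provenance attached to every row; `fluid` must be
#'   "plasma" or "urine" (or NA).
#' @return Variant data frame (see [empty_variants()] for the schema).
#' @export
read_sample_vcf <- function(path, tag_config = default_tag_config(),
                            sample_id = NA_character_, fluid = NA_character_) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  n_body <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (n_body == 0L) {
    out <- empty_variants()
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (!identical(tag_config$call_quality, "QUAL"))
    qual <- info_or_default(vcf, tag_config$call_quality, NA, numeric = TRUE)

  vaf_raw <- suppressWarnings(vcfR::extract.info(vcf, element = tag_config$vaf))
  pop_raw <- suppressWarnings(vcfR::extract.info(vcf, element = tag_config$pop_af))
  gene <- info_or_default(vcf, tag_config$gene, NA_character_)
  effect <- info_or_default(vcf, tag_config$effect, "other")
  intoff <- as.integer(info_or_default(vcf, tag_config$intron_offset, 0, numeric = TRUE))
  spl <- info_or_default(vcf, tag_config$splice_pred, 0, numeric = TRUE) != 0
  gof <- info_or_default(vcf, tag_config$gof, 0, numeric = TRUE) != 0
  lof <- info_or_default(vcf, tag_config$lof, 0, numeric = TRUE) != 0
  evid <- info_or_default(vcf, tag_config$evidence, "")
  clin <- info_or_default(vcf, tag_config$clinical_evidence, "none")
  estp <- info_or_default(vcf, tag_config$established_pathogenic, 0, numeric = TRUE) != 0

  has_gt <- nrow(vcf@gt) > 0 && ncol(vcf@gt) >= 2
  ad <- if (has_gt) vcfR::extract.gt(vcf, element = "AD")[, 1] else rep(NA_character_, n)
  dp <- if (has_gt) suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1]))
        else rep(NA_real_, n)

  alts_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alts <- lengths(alts_list)
  idx <- rep.int(seq_len(n), n_alts)               # record index per row
  jdx <- unlist(lapply(n_alts, seq_len))           # allele index per row

  # per-allele tag values: split on commas when the count matches the
  # number of ALT alleles, otherwise recycle the single value
  split_a <- function(raw) {
    if (is.null(raw)) return(rep(NA_real_, length(idx)))
    parts <- strsplit(as.character(raw), ",", fixed = TRUE)
    suppressWarnings(as.numeric(unlist(lapply(seq_len(n), function(i) {
      p <- parts[[i]]
      if (length(p) == 0L || is.na(raw[i])) rep(NA_character_, n_alts[i])
      else if (length(p) == n_alts[i]) p
      else rep(p[1], n_alts[i])
    }))))
  }
  vafs <- split_a(vaf_raw)
  pops <- split_a(pop_raw)

  miss <- is.na(vafs)
  if (any(miss)) {   # AD/DP ratio fallback, per ALT allele
    ad_list <- strsplit(ad, ",", fixed = TRUE)
    for (r in which(miss)) {
      i <- idx[r]; j <- jdx[r]
      ad_i <- suppressWarnings(as.numeric(ad_list[[i]]))
      if (!is.na(ad[i]) && length(ad_i) >= j + 1 && !is.na(dp[i]) && dp[i] > 0)
        vafs[r] <- 100 * ad_i[j + 1] / dp[i]
      else stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                " has no VAF tag and no AD/DP fallback")
    }
  }

  out <- data.frame(
    chrom = fix[idx, "CHROM"], pos = as.integer(fix[idx, "POS"]),
    ref = toupper(fix[idx, "REF"]), alt = toupper(unlist(alts_list)),
    gene = gene[idx], call_quality = qual[idx], vaf = vafs,
    depth = as.integer(round(dp[idx])), pop_af = pops,
    effect = effect[idx], intron_offset = intoff[idx],
    splice_pred_flag = spl[idx], gof_flag = gof[idx], lof_flag = lof[idx],
    evidence_codes = evid[idx], clinical_evidence_level = clin[idx],
    established_pathogenic = estp[idx],
    sample_id = sample_id, fluid = fluid, key = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out <- normalize_variants(out)
  validate_variants(out)
  out
}

#' Write a variant table as an annotated VCF
#'
#' Emits a plain-text VCF v4.2 carrying the pipeline's annotation dialect
#' (GENE, VAFPCT, POPAF, EFFECT, INTOFF, SPLICEPRED, GOF, LOF, EVID, CLINEVID,
#' ESTPATH as INFO tags; DP and AD in FORMAT) plus any extra String INFO
#' columns named in `extra_info`. Booleans are written as Integer 0/1.
#' AD is reconstructed from depth and VAF. Output is deterministic for a
#' given table.
#'
#' @param variants Variant data frame.
#' @param path Output file path.
#' @param sample_name Sample column name.
#' @param extra_info Named list mapping INFO tag -> character vector (one
#'   value per row), e.g. class/tier/bin annotations.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(variants, path, sample_name = "SAMPLE",
                             extra_info = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnaconcord",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="HGNC gene symbol">',
    '##INFO=<ID=VAFPCT,Number=A,Type=Float,Description="Variant allele fraction, percent">',
    '##INFO=<ID=POPAF,Number=A,Type=Float,Description="Maximum population allele fraction (0-1)">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Predicted effect">',
    '##INFO=<ID=INTOFF,Number=1,Type=Integer,Description="Signed distance into intron, 0 if exonic">',
    '##INFO=<ID=SPLICEPRED,Number=1,Type=Integer,Description="External splice-disruption prediction (0/1)">',
    '##INFO=<ID=GOF,Number=1,Type=Integer,Description="Gain-of-function association (0/1)">',
    '##INFO=<ID=LOF,Number=1,Type=Integer,Description="Loss-of-function association (0/1)">',
    '##INFO=<ID=EVID,Number=1,Type=String,Description="Comma-separated ACMG/AMP evidence codes">',
    '##INFO=<ID=CLINEVID,Number=1,Type=String,Description="Clinical evidence level A/B/C/D/none">',
    '##INFO=<ID=ESTPATH,Number=1,Type=Integer,Description="Established pathogenic variant (0/1)">'
  )
  if (!is.null(extra_info))
    hdr <- c(hdr, sprintf(
      '##INFO=<ID=%s,Number=1,Type=String,Description="Pipeline annotation">',
      names(extra_info)))
  hdr <- c(hdr,
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))

  body <- character(0)
  if (nrow(variants) > 0L) {
    num <- function(x) formatC(x, format = "g", digits = 10)
    v <- variants
    segs <- cbind(
      ifelse(is.na(v$gene), NA, paste0("GENE=", v$gene)),
      paste0("VAFPCT=", num(v$vaf)),
      ifelse(is.na(v$pop_af), NA, paste0("POPAF=", num(v$pop_af))),
      paste0("EFFECT=", v$effect),
      paste0("INTOFF=", v$intron_offset),
      paste0("SPLICEPRED=", as.integer(v$splice_pred_flag)),
      paste0("GOF=", as.integer(v$gof_flag)),
      paste0("LOF=", as.integer(v$lof_flag)),
      ifelse(nzchar(v$evidence_codes), paste0("EVID=", v$evidence_codes), NA),
      paste0("CLINEVID=", v$clinical_evidence_level),
      paste0("ESTPATH=", as.integer(v$established_pathogenic))
    )
    if (!is.null(extra_info))
      for (tag in names(extra_info))
        segs <- cbind(segs, paste0(tag, "=", extra_info[[tag]]))
    info <- apply(segs, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
    depth <- ifelse(is.na(v$depth), 1000L, v$depth)
    ad_alt <- round(depth * v$vaf / 100)
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, num(v$call_quality),
                  "PASS", info, "DP:AD",
                  paste0(depth, ":", depth - ad_alt, ",", ad_alt), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cfDNA concentration table
#'
#' @param path CSV with header `patient_id, plasma_ng_ml, urine_ng_ml`;
#'   concentrations in ng/mL, zero allowed (undetectable cfDNA).
#' @return Data frame with those three columns.
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "plasma_ng_ml", "urine_ng_ml")
  if (!identical(names(df)[seq_along(need)], need))
    stop("concentration CSV must have header: ", paste(need, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in concentration table")
  conc <- c(df$plasma_ng_ml, df$urine_ng_ml)
  if (any(is.na(conc)) || any(conc < 0))
    stop("concentrations must be non-negative numbers")
  df[need]
}

#' Read an exclusion-window BED file
#'
#' BED3, 0-based half-open. The windows mark regions excluded by the
#' confidence filter (e.g. the most exonically variable 100-base windows in
#' healthy genomes, consumed as a precomputed track).
#'
#' @param path BED3 file path.
#' @return Data frame with columns chrom, start, end ("chr" prefix stripped).
#' @export
read_window_bed <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop("BED interval with start >= end")
  df
}

#' Test membership of 1-based positions in a 0-based half-open window set
#'
#' A 1-based position `pos` lies in window `[start, end)` (0-based half-open)
#' iff `start < pos <= end`. This is the only place the two coordinate
#' conventions meet.
#'
#' @param windows Data frame from [read_window_bed()].
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
window_contains <- function(windows, chrom, pos) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (nrow(windows) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(windows$chrom == chrom[i] & windows$start < pos[i] &
          pos[i] <= windows$end)
  }, logical(1))
}
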