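ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "VUS",
                  "likely_benign", "benign")

TIERS <- c("I", "II", "III", "IV")

VAF_BIN_BREAKS <- c(3, 5, 10, 20, 50, 100)
VAF_BIN_LABELS <- c("3-5", "5-10", "10-20", "20-50", "50-100")

count_codes <- function(codes) {
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad))
    stop("unknown evidence code(s): ", paste(unique(bad), collapse = ", "))
  c(pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS", codes)),
    pm = sum(grepl("^PM", codes)),
    pp = sum(grepl("^PP", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS", codes)),
    bp = sum(grepl("^BP", codes)))
}

#' ACMG/AMP five-class impact classification from evidence codes
#'
#' Combines ACMG/AMP 2015 evidence codes (PVS1, PS1-PS4, PM1-PM6, PP1-PP5,
#' BA1, BS1-BS4, BP1-BP7) into one of five classes by the standard combining
#' rules:
#'
#' * Pathogenic: PVS1 with (>=1 PS, or >=2 PM, or 1 PM + 1 PP, or >=2 PP);
#'   or >=2 PS; or 1 PS with (>=3 PM, or 2 PM + >=2 PP, or 1 PM + >=4 PP).
#' * Likely pathogenic: PVS1 + 1 PM; 1 PS + 1-2 PM; 1 PS + >=2 PP; >=3 PM;
#'   2 PM + >=2 PP; 1 PM + >=4 PP.
#' * Benign: BA1, or >=2 BS.
#' * Likely benign: 1 BS + 1 BP, or >=2 BP.
#' * Otherwise, or when a pathogenic-side and a benign-side rule both fire,
#'   the variant is of uncertain significance (VUS).
#'
#' Duplicated code tokens are counted once.
#'
#' @param codes Character vector of evidence codes, or a single
#'   comma-separated string (the VCF EVID encoding). An empty set is legal
#'   and classifies as VUS.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' acmg_classify(c("PVS1", "PS1"))   # pathogenic
#' acmg_classify(character(0))       # VUS
#' acmg_classify("BA1,PVS1,PS1")     # conflicting evidence -> VUS
#' @export
acmg_classify <- function(codes) {
  if (length(codes) == 1L && grepl(",", codes))
    codes <- strsplit(codes, ",", fixed = TRUE)[[1]]
  n <- count_codes(unique(trimws(as.character(codes))))

  pathogenic <-
    (n["pvs"] >= 1 && (n["ps"] >= 1 || n["pm"] >= 2 ||
                       (n["pm"] == 1 && n["pp"] >= 1) || n["pp"] >= 2)) ||
    n["ps"] >= 2 ||
    (n["ps"] == 1 && (n["pm"] >= 3 ||
                      (n["pm"] == 2 && n["pp"] >= 2) ||
                      (n["pm"] == 1 && n["pp"] >= 4)))
  likely_path <-
    (n["pvs"] >= 1 && n["pm"] == 1) ||
    (n["ps"] == 1 && n["pm"] >= 1 && n["pm"] <= 2) ||
    (n["ps"] == 1 && n["pp"] >= 2) ||
    n["pm"] >= 3 ||
    (n["pm"] == 2 && n["pp"] >= 2) ||
    (n["pm"] == 1 && n["pp"] >= 4)
  benign <- n["ba"] >= 1 || n["bs"] >= 2
  likely_benign <- (n["bs"] == 1 && n["bp"] >= 1) || n["bp"] >= 2

  path_side <- pathogenic || likely_path
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("pathogenic")
  if (likely_path) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "VUS"
}

#' AMP/ASCO/CAP four-tier clinical significance
#'
#' Benign and likely benign variants fall in tier IV; otherwise clinical
#' evidence level A/B gives tier I (strong clinical significance), C/D gives
#' tier II (potential clinical significance), and no evidence gives tier III
#' (unknown clinical significance).
#'
#' @param acmg_class Character vector of ACMG classes.
#' @param clinical_evidence_level Character vector over A/B/C/D/none.
#' @return Character vector over "I", "II", "III", "IV".
#' @export
assign_tier <- function(acmg_class, clinical_evidence_level) {
  stopifnot(length(acmg_class) == length(clinical_evidence_level))
  ifelse(acmg_class %in% c("benign", "likely_benign"), "IV",
    ifelse(clinical_evidence_level %in% c("A", "B"), "I",
      ifelse(clinical_evidence_level %in% c("C", "D"), "II", "III")))
}

#' VAF abundance bin
#'
#' Partitions post-cascade VAF values (percent) into the five abundance
#' groups 3-5, 5-10, 10-20, 20-50 and 50-100. Bins are left-closed
#' half-open, with the last bin closed at 100, so the bins partition
#' \[3, 100\].
#'
#' @param vaf_pct Numeric vector of VAF percentages in \[3, 100\].
#' @return Factor with levels "3-5", "5-10", "10-20", "20-50", "50-100".
#' @export
vaf_bin <- function(vaf_pct) {
  if (any(is.na(vaf_pct)) || any(vaf_pct < 3 | vaf_pct > 100))
    stop("vaf out of domain: binning is defined on [3, 100]")
  cut(vaf_pct, breaks = VAF_BIN_BREAKS, labels = VAF_BIN_LABELS,
      right = FALSE, include.lowest = TRUE)
}

#' Annotate a variant table with class, tier and VAF bin
#'
#' Adds `acmg_class` (from the evidence codes), `tier` (from class and
#' clinical evidence level) and, when every VAF lies in \[3, 100\], `vaf_bin`.
#'
#' @param variants Variant data frame.
#' @return The data frame with the added columns.
#' @export
classify_variants <- function(variants) {
  if (nrow(variants) == 0L) {
    variants$acmg_class <- character(0)
    variants$tier <- character(0)
    variants$vaf_bin <- factor(character(0), levels = VAF_BIN_LABELS)
    return(variants)
  }
  variants$acmg_class <- vapply(variants$evidence_codes, acmg_classify,
                                character(1), USE.NAMES = FALSE)
  variants$tier <- assign_tier(variants$acmg_class,
                               variants$clinical_evidence_level)
  variants$vaf_bin <- if (all(variants$vaf >= 3 & variants$vaf <= 100))
    vaf_bin(variants$vaf)
  else
    factor(rep(NA_character_, nrow(variants)), levels = VAF_BIN_LABELS)
  variants
}
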