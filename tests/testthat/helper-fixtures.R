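# Builders for in-code fixtures; no fixture files on disk.

# One variant row with sensible survivor defaults; override any field.
make_variant <- function(...) {
  v <- list(
    chrom = "1", pos = 1000L, ref = "G", alt = "A", gene = "TP53",
    call_quality = 120, vaf = 25, depth = 500L, pop_af = 0.001,
    effect = "missense", intron_offset = 0L, splice_pred_flag = FALSE,
    gof_flag = FALSE, lof_flag = FALSE, evidence_codes = "",
    clinical_evidence_level = "none", established_pathogenic = FALSE,
    sample_id = "S1", fluid = "plasma", key = NA_character_
  )
  over <- list(...)
  v[names(over)] <- over
  df <- do.call(data.frame, c(v, stringsAsFactors = FALSE))
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

make_variants <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Cached synthetic cohorts so several test files can share one generation.
.cohort_cache <- new.env(parent = emptyenv())
cohort_fixture <- function(n_patients, seed, shared_fraction = 0.47) {
  key <- paste(n_patients, seed, shared_fraction, sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  outdir <- file.path(tempdir(), paste0("cohort_", key))
  cfg <- synthetic_config(n_patients = n_patients, seed = seed,
                          shared_fraction = shared_fraction)
  g <- generate_cohort(cfg, outdir)
  res <- run_pipeline(g$paths$manifest_tsv, g$paths$concentrations_csv,
                      g$paths$windows_bed)
  .cohort_cache[[key]] <- list(gen = g, res = res)
  .cohort_cache[[key]]
}

# Independent enumeration oracle for the paired Wilcoxon exact p-value:
# all 2^n sign assignments of the non-zero differences (no ties allowed).
wilcoxon_enum_p <- function(x, y) {
  d <- (x - y)[x != y]
  stopifnot(!anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(2 * min(p_le, p_ge), 1)
}

# Independent mid-rank Spearman oracle: explicit average ranks, then the
# Pearson product-moment formula written out.
spearman_midrank_oracle <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) {
      less <- sum(v < vi)
      eq <- sum(v == vi)
      less + (eq + 1) / 2
    })
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent transcription of the ACMG/AMP combining rules: flat lists of
# minimum-count requirements, evaluated generically, pathogenic checked
# before likely pathogenic and the conflict rule applied on the side flags.
acmg_oracle <- function(codes) {
  n <- c(pvs = sum(codes == "PVS1"),
         ps = sum(codes %in% paste0("PS", 1:4)),
         pm = sum(codes %in% paste0("PM", 1:6)),
         pp = sum(codes %in% paste0("PP", 1:5)),
         ba = sum(codes == "BA1"),
         bs = sum(codes %in% paste0("BS", 1:4)),
         bp = sum(codes %in% paste0("BP", 1:7)))
  meets <- function(rules) any(vapply(rules, function(r)
    all(n[names(r)] >= r), logical(1)))
  path <- meets(list(
    c(pvs = 1, ps = 1), c(pvs = 1, pm = 2), c(pvs = 1, pm = 1, pp = 1),
    c(pvs = 1, pp = 2), c(ps = 2), c(ps = 1, pm = 3),
    c(ps = 1, pm = 2, pp = 2), c(ps = 1, pm = 1, pp = 4)))
  lp <- meets(list(
    c(pvs = 1, pm = 1), c(ps = 1, pm = 1), c(ps = 1, pp = 2),
    c(pm = 3), c(pm = 2, pp = 2), c(pm = 1, pp = 4)))
  ben <- meets(list(c(ba = 1), c(bs = 2)))
  lb <- meets(list(c(bs = 1, bp = 1), c(bp = 2)))
  if ((path || lp) && (ben || lb)) return("VUS")
  if (path) return("pathogenic")
  if (lp) return("likely_pathogenic")
  if (ben) return("benign")
  if (lb) return("likely_benign")
  "VUS"
}

# All subsets of the evidence-code alphabet up to a given size.
code_subsets <- function(max_size) {
  codes <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  out <- list(character(0))
  for (k in seq_len(max_size))
    out <- c(out, combn(codes, k, simplify = FALSE))
  out
}
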