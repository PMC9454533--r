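#' Normalize a variant to its canonical minimal representation
#'
#' Shared trailing bases are trimmed first, then shared leading bases are
#' trimmed with the position advanced. When a reference context is supplied,
#' indels are additionally left-aligned: whenever trimming would empty an
#' allele, the reference base preceding the variant is prepended and the
#' position moved left, so a deletion or insertion inside a homopolymer or
#' tandem repeat ends at its leftmost placement. The result is idempotent.
#'
#' Variant identity throughout the pipeline is the normalized
#' (chrom, pos, ref, alt) tuple; matched-fluid "shared variant" calls are only
#' well-defined on this canonical form.
#'
#' @param chrom Chromosome name; an optional "chr" prefix is stripped.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt Allele strings over A/C/G/T; must differ.
#' @param context Optional reference sequence string used for left-alignment.
#' @param context_start 1-based genomic position of the first base of
#'   `context`. Required when `context` is given.
#' @return A list with elements `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("1", 100, "AT", "AC")   # -> pos 101, T>C
#' normalize_variant("2", 500, "G", "T")     # SNVs are untouched
#' @export
normalize_variant <- function(chrom, pos, ref, alt,
                              context = NULL, context_start = NULL) {
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (is.na(pos) || pos < 1L) stop("invalid variant: pos must be >= 1")
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("invalid variant: alleles must be non-empty strings over A,C,G,T")
  if (ref == alt) stop("invalid variant: ref == alt")
  if (!is.null(context) && is.null(context_start))
    stop("context_start is required when context is given")

  base_at <- function(p) {
    i <- p - context_start + 1L
    if (i < 1L || i > nchar(context)) NA_character_
    else substr(context, i, i)
  }

  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr > 1L && na > 1L) {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
      } else if (!is.null(context)) {
        b <- base_at(pos - 1L)
        if (is.na(b)) break  # context exhausted; leave as is
        ref <- paste0(b, substr(ref, 1L, nr - 1L))
        alt <- paste0(b, substr(alt, 1L, na - 1L))
        pos <- pos - 1L
      } else break
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop("invalid variant: alleles identical after trimming")
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Normalize every variant row of a variant table
#'
#' Applies [normalize_variant()] row-wise and recomputes the `key` column.
#'
#' @param variants A variant data frame with columns chrom, pos, ref, alt.
#' @return The data frame with normalized coordinates/alleles and a `key`
#'   column of canonical identity strings.
#' @export
normalize_variants <- function(variants) {
  if (nrow(variants) == 0L) {
    variants$key <- character(0)
    return(variants)
  }
  norm <- lapply(seq_len(nrow(variants)), function(i) {
    normalize_variant(variants$chrom[i], variants$pos[i],
                      variants$ref[i], variants$alt[i])
  })
  variants$chrom <- vapply(norm, `[[`, character(1), "chrom")
  variants$pos <- vapply(norm, `[[`, integer(1), "pos")
  variants$ref <- vapply(norm, `[[`, character(1), "ref")
  variants$alt <- vapply(norm, `[[`, character(1), "alt")
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  variants
}

#' Canonical variant identity string
#'
#' @param chrom,pos,ref,alt Normalized variant coordinates (vectorized).
#' @return Character vector "chrom:pos:ref:alt" with any "chr" prefix removed.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(sub("^chr", "", as.character(chrom)), as.integer(pos),
        toupper(ref), toupper(alt), sep = ":")
}
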