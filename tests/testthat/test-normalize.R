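test_that("trailing and leading trimming gives the minimal representation", {
  expect_equal(normalize_variant("1", 100, "AT", "AC"),
               list(chrom = "1", pos = 101L, ref = "T", alt = "C"))
  expect_equal(normalize_variant("2", 500, "G", "T"),
               list(chrom = "2", pos = 500L, ref = "G", alt = "T"))
  # multi-base: trailing first, then leading with pos advance
  expect_equal(normalize_variant("5", 200, "CAGG", "CTGG"),
               list(chrom = "5", pos = 201L, ref = "A", alt = "T"))
  # chr prefix is stripped for identity purposes
  expect_equal(normalize_variant("chr7", 10, "A", "C")$chrom, "7")
})

test_that("invalid variants are rejected", {
  expect_error(normalize_variant("1", 0, "A", "C"), "pos")
  expect_error(normalize_variant("1", 5, "A", "A"), "ref == alt")
  expect_error(normalize_variant("1", 5, "", "C"), "alleles")
  expect_error(normalize_variant("1", 5, "AN", "A"), "alleles")
  # identical after trimming
  expect_error(normalize_variant("1", 5, "CA", "CA"), "ref == alt")
})

test_that("normalization is idempotent over random representations", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    core_r <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    core_a <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    if (core_r == core_a) next
    pad_l <- paste(sample(bases, sample(0:2, 1), TRUE), collapse = "")
    pad_r <- paste(sample(bases, sample(0:2, 1), TRUE), collapse = "")
    v1 <- normalize_variant("3", 50, paste0(pad_l, core_r, pad_r),
                            paste0(pad_l, core_a, pad_r))
    v2 <- do.call(normalize_variant, v1)
    expect_identical(v1, v2)
  }
})

test_that("padded representations of one variant collapse to one key", {
  a <- normalize_variant("2", 99, "TAC", "TTC")   # pad both sides
  b <- normalize_variant("2", 100, "A", "T")
  expect_identical(a, b)
})

# Brute-force oracle: all equivalent (pos, ref, alt) representations over a
# reference context (equal edited haplotype), canonical = minimal combined
# allele length, then minimal position.
enumerate_equivalents <- function(context, context_start, pos, ref, alt) {
  apply_variant <- function(p, r, a) {
    i <- p - context_start + 1L
    if (substr(context, i, i + nchar(r) - 1L) != r) return(NULL)
    paste0(substr(context, 1L, i - 1L), a,
           substr(context, i + nchar(r), nchar(context)))
  }
  target <- apply_variant(pos, ref, alt)
  stopifnot(!is.null(target))
  reps <- list()
  for (p in seq(context_start, context_start + nchar(context) - 1L)) {
    i <- p - context_start + 1L
    for (len in 1:4) {
      if (i + len - 1L > nchar(context)) next
      r <- substr(context, i, i + len - 1L)
      # alt is forced by requiring the edited haplotype to equal the target
      pre <- substr(context, 1L, i - 1L)
      post <- substr(context, i + len, nchar(context))
      if (!startsWith(target, pre) || !endsWith(target, post)) next
      a <- substr(target, nchar(pre) + 1L, nchar(target) - nchar(post))
      if (!nzchar(a) || a == r) next
      if (!grepl("^[ACGT]+$", a)) next
      reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
    }
  }
  lens <- vapply(reps, function(x) nchar(x$ref) + nchar(x$alt), integer(1))
  reps <- reps[lens == min(lens)]
  poss <- vapply(reps, `[[`, integer(1), "pos")
  reps[[which.min(poss)]]
}

test_that("context left-alignment matches the brute-force oracle", {
  # homopolymer: deleting one A from the run in C AAAA G
  context <- "GTCAAAAG"   # positions 101..108
  oracle <- enumerate_equivalents(context, 101L, 105L, "AA", "A")
  got <- normalize_variant("3", 105, "AA", "A",
                           context = context, context_start = 101L)
  expect_equal(got[c("pos", "ref", "alt")], oracle)
  expect_equal(got$pos, 103L)   # leftmost anchor base C
  # tandem repeat: deleting one AC unit from G ACACAC T
  context2 <- "TGACACACT"  # positions 201..209
  oracle2 <- enumerate_equivalents(context2, 201L, 206L, "CAC", "C")
  got2 <- normalize_variant("4", 206, "CAC", "C",
                            context = context2, context_start = 201L)
  expect_equal(got2[c("pos", "ref", "alt")], oracle2)
  # insertions too
  oracle3 <- enumerate_equivalents(context, 101L, 106L, "A", "AAA")
  got3 <- normalize_variant("3", 106, "A", "AAA",
                            context = context, context_start = 101L)
  expect_equal(got3[c("pos", "ref", "alt")], oracle3)
})

test_that("variant keys are representation-invariant", {
  df <- make_variants(
    make_variant(pos = 100L, ref = "AT", alt = "AC"),
    make_variant(pos = 101L, ref = "T", alt = "C", gene = "ATM")
  )
  norm <- normalize_variants(df)
  expect_identical(norm$key[1], norm$key[2])
})
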