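no_windows <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))

test_that("confidence filter applies inclusive thresholds in documented order", {
  win <- data.frame(chrom = "1", start = 100L, end = 200L)
  df <- make_variants(
    make_variant(pos = 1000L, call_quality = 49, vaf = 10),        # quality
    make_variant(pos = 2000L, call_quality = 50, vaf = 3.0),       # kept: edges
    make_variant(pos = 3000L, call_quality = 90, vaf = 2.9),       # vaf
    make_variant(pos = 150L, call_quality = 90, vaf = 40),         # window
    make_variant(pos = 4000L, call_quality = 49, vaf = 1,
                 ref = "C", alt = "G")                             # both fail
  )
  res <- confidence_filter(df, filter_config(), win)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$kept$pos, 2000L)
  # first failing reason in order quality, vaf, window
  expect_equal(res$removed$reason[match(c(1000L, 3000L, 150L, 4000L),
                                        res$removed$pos)],
               c("quality", "vaf", "window", "quality"))
})

test_that("common filter removes prevalent variants unless established pathogenic", {
  df <- make_variants(
    make_variant(pos = 1L, pop_af = 0.02),
    make_variant(pos = 2L, pop_af = 0.02, established_pathogenic = TRUE),
    make_variant(pos = 3L, pop_af = NA_real_),   # absent from databases
    make_variant(pos = 4L, pop_af = 0.01)        # inclusive keep edge
  )
  res <- common_filter(df, filter_config())
  expect_setequal(res$kept$pos, c(2L, 3L, 4L))
  expect_equal(res$removed$pos, 1L)
  expect_equal(res$removed$reason, "common")
})

test_that("deleterious filter combines intron distance with retention clauses", {
  df <- make_variants(
    make_variant(pos = 1L, effect = "missense", intron_offset = 21L),
    make_variant(pos = 2L, effect = "synonymous", evidence_codes = "BS1,BS2"),
    make_variant(pos = 3L, effect = "missense", evidence_codes = ""),
    make_variant(pos = 4L, effect = "splice_region", intron_offset = 2L,
                 evidence_codes = "BS1,BS2"),
    make_variant(pos = 5L, effect = "splice_region", intron_offset = 3L,
                 evidence_codes = "BS1,BS2"),
    make_variant(pos = 6L, effect = "synonymous", evidence_codes = "BS1,BS2",
                 gof_flag = TRUE),
    make_variant(pos = 7L, effect = "intronic", intron_offset = 18L),
    make_variant(pos = 8L, effect = "synonymous", evidence_codes = "BS1,BS2",
                 splice_pred_flag = TRUE)
  )
  res <- deleterious_filter(df, filter_config())
  # 1: offset 21 out; 2: benign synonymous out; 5: splice beyond 2b, benign out
  expect_setequal(res$kept$pos, c(3L, 4L, 6L, 7L, 8L))
  expect_equal(res$removed$reason[match(c(1L, 2L, 5L), res$removed$pos)],
               c("intron_offset", "not_deleterious", "not_deleterious"))
})

test_that("cascade composes the three stages and reports planted attrition", {
  # planted fates: 3 low-quality, 2 common non-pathogenic, 1 deep-intronic
  # benign, 4 clean -> 4 survivors with reason counts 3/2/1
  clean <- function(pos) make_variant(pos = pos)
  lowq <- function(pos) make_variant(pos = pos, call_quality = 30)
  common <- function(pos) make_variant(pos = pos, pop_af = 0.05)
  deep <- make_variant(pos = 999L, effect = "intronic", intron_offset = 40L,
                       evidence_codes = "BS1,BS2")
  df <- make_variants(lowq(1L), lowq(2L), lowq(3L), common(11L), common(12L),
                      deep, clean(21L), clean(22L), clean(23L), clean(24L))
  res <- run_cascade(df, filter_config(), no_windows)
  expect_setequal(res$kept$pos, c(21L, 22L, 23L, 24L))
  rep <- res$report
  expect_equal(rep$n_removed, c(3L, 2L, 1L))
  expect_equal(rep$quality[rep$stage == "confidence"], 3L)
  expect_equal(rep$common[rep$stage == "common"], 2L)
  expect_equal(rep$intron_offset[rep$stage == "deleterious"], 1L)
  # stage chaining: surviving(stage k) == input(stage k+1)
  expect_equal(rep$n_out[-3], rep$n_in[-1])
  # fused == staged composition
  s1 <- confidence_filter(df, filter_config(), no_windows)
  s2 <- common_filter(s1$kept, filter_config())
  s3 <- deleterious_filter(s2$kept, filter_config())
  expect_identical(res$kept$key, s3$kept$key)
})

test_that("empty input yields empty output with zero counts", {
  res <- run_cascade(empty_variants(), filter_config(), no_windows)
  expect_equal(nrow(res$kept), 0L)
  expect_true(all(res$report$n_in == 0L))
  expect_true(all(res$report$n_removed == 0L))
})

test_that("each filter is idempotent and attrition is monotone", {
  set.seed(21)
  g <- cohort_fixture(3, 555)
  v <- do.call(rbind, lapply(g$gen$manifest$plasma_vcf, read_sample_vcf))
  v$sample_id <- "pool"
  win <- read_window_bed(g$gen$paths$windows_bed)
  res <- run_cascade(v, filter_config(), win)
  expect_true(all(diff(res$report$n_out) <= 0))
  for (f in list(function(x) confidence_filter(x, filter_config(), win),
                 function(x) common_filter(x, filter_config()),
                 function(x) deleterious_filter(x, filter_config()))) {
    once <- f(res$kept)
    twice <- f(once$kept)
    expect_identical(once$kept$key, twice$kept$key)
    expect_equal(nrow(twice$removed), 0L)
  }
})
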