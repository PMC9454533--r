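test_that("seed is mandatory and config validates", {
  expect_error(synthetic_config(n_patients = 2), "seed")
  expect_error(synthetic_config(seed = 1, shared_fraction = 1.5))
  expect_error(synthetic_config(seed = 1, vaf_bin_masses = rep(-1, 5)))
})

test_that("identical seed and config give byte-identical cohorts", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  cfg <- synthetic_config(n_patients = 3, seed = 9001)
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1))
  f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  md5 <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_identical(md5(d1, f1), md5(d2, f2))
  # a different seed changes the files
  d3 <- file.path(tempdir(), "det3")
  generate_cohort(synthetic_config(n_patients = 3, seed = 9002), d3)
  expect_false(identical(md5(d1, f1), md5(d3, sort(list.files(d3)))))
})

test_that("an empty cohort writes empty files and empty truth", {
  d <- file.path(tempdir(), "empty_cohort")
  g <- generate_cohort(synthetic_config(n_patients = 0, seed = 5), d)
  expect_equal(nrow(g$manifest), 0L)
  expect_equal(nrow(g$truth), 0L)
  expect_equal(nrow(g$concentrations), 0L)
  expect_true(file.exists(g$paths$manifest_tsv))
})

test_that("VAF sampler hits the configured bin masses", {
  set.seed(77)
  # degenerate config: all mass on the top bin
  x <- sample_vaf(500, c(0, 0, 0, 0, 1))
  expect_true(all(x >= 50 & x <= 100))
  # default masses at 1e4 draws: within 3 sigma per bin
  masses <- c(0.37, 0.32, 0.19, 0.10, 0.02)
  n <- 10000
  draws <- sample_vaf(n, masses)
  emp <- as.numeric(table(vaf_bin(draws))) / n
  se <- sqrt(masses * (1 - masses) / n)
  expect_true(all(abs(emp - masses) <= 3 * se))
  expect_true(all(draws >= 3 & draws <= 100))
})

test_that("fixed seed reproduces the draw sequence", {
  set.seed(123); a <- sample_vaf(50)
  set.seed(123); b <- sample_vaf(50)
  expect_identical(a, b)
})

test_that("planted removals violate exactly their own criterion", {
  g <- cohort_fixture(3, 555)
  truth <- g$gen$truth
  win <- read_window_bed(g$gen$paths$windows_bed)
  cfg <- filter_config()
  for (i in seq_len(nrow(g$gen$manifest))) {
    for (fluid in c("plasma", "urine")) {
      v <- read_sample_vcf(g$gen$manifest[[paste0(fluid, "_vcf")]][i],
                           sample_id = g$gen$manifest$patient_id[i],
                           fluid = fluid)
      tt <- truth[truth$patient_id == g$gen$manifest$patient_id[i] &
                    truth$fluid == fluid, ]
      v <- v[match(tt$key, v$key), ]
      fate <- tt$fate
      lowq <- fate == "confidence:quality"
      expect_true(all(v$call_quality[lowq] < 50))
      expect_true(all(v$vaf[lowq] >= 3))           # fails only quality
      lowv <- fate == "confidence:vaf"
      expect_true(all(v$vaf[lowv] < 3 & v$vaf[lowv] >= 0.1))
      expect_true(all(v$call_quality[lowv] >= 50))
      winp <- fate == "confidence:window"
      expect_true(all(window_contains(win, v$chrom[winp], v$pos[winp])))
      comm <- fate == "common:common"
      expect_true(all(v$pop_af[comm] > 0.01 & v$pop_af[comm] <= 0.5))
      expect_true(all(!v$established_pathogenic[comm]))
      deep <- fate == "deleterious:intron_offset"
      expect_true(all(abs(v$intron_offset[deep]) > 20))
    }
  }
})

test_that("the cascade removes exactly the planted records at the planted stages", {
  g <- cohort_fixture(3, 555)
  truth <- g$gen$truth
  win <- read_window_bed(g$gen$paths$windows_bed)
  for (i in seq_len(nrow(g$gen$manifest))) {
    pid <- g$gen$manifest$patient_id[i]
    for (fluid in c("plasma", "urine")) {
      v <- read_sample_vcf(g$gen$manifest[[paste0(fluid, "_vcf")]][i],
                           sample_id = pid, fluid = fluid)
      res <- run_cascade(v, filter_config(), win)
      tt <- truth[truth$patient_id == pid & truth$fluid == fluid, ]
      want_survive <- sort(tt$key[tt$fate == "survive"])
      expect_identical(sort(res$kept$key), want_survive)
      got_fate <- paste(res$removed$stage, res$removed$reason, sep = ":")
      want <- tt[tt$fate != "survive", ]
      expect_identical(got_fate[match(want$key, res$removed$key)], want$fate)
    }
  }
})

test_that("generator parameters are recovered by the pipeline", {
  g <- cohort_fixture(3, 555)
  truth <- g$gen$truth
  surv <- truth[truth$fate == "survive", ]
  # class labels planted = classes called by the classifier
  v <- g$res$survivors
  sk <- paste(surv$patient_id, surv$fluid, surv$key)
  vk <- paste(v$sample_id, v$fluid, v$key)
  expect_identical(v$acmg_class[match(sk, vk)], surv$class_label)
  # per-gene counts equal the planted per-gene counts
  planted <- table(surv$gene)
  got <- g$res$summary$gene_table
  expect_equal(got$total[match(names(planted), got$gene)],
               as.integer(planted))
})

test_that("concentration correlation parameter is recovered at n = 100", {
  # keep per-sample variant counts minimal: only the concentration draws
  # (cohort-level stream) matter here
  cfg <- synthetic_config(n_patients = 100, seed = 31415,
                          plasma_median_count = 5, urine_median_count = 5,
                          removal_rates = c(quality = 0, vaf = 0, window = 0,
                                            common = 0, intron_offset = 0,
                                            not_deleterious = 0))
  g <- generate_cohort(cfg, file.path(tempdir(), "conc100"))
  conc <- g$concentrations
  r <- spearman_rho(conc$plasma_ng_ml, conc$urine_ng_ml)
  expect_lt(abs(r$statistic - (-0.19)), 0.15)
})
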