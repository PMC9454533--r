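keyed <- function(keys, fluid = "plasma", sample_id = "S1", class = "VUS") {
  data.frame(key = keys, fluid = fluid, sample_id = sample_id,
             acmg_class = class, stringsAsFactors = FALSE)
}

test_that("recovery rate is the shared fraction of the source set", {
  expect_equal(recovery_rate(c("a", "b"), c("b", "c")), 50)
  expect_true(is.na(recovery_rate(character(0), "b")))
  expect_equal(recovery_rate(letters[1:10], letters[1:10]), 100)
  # symmetric numerator: |A intersect B| identical in both directions
  set.seed(31)
  for (i in 1:25) {
    a <- sample(letters, sample(3:15, 1))
    b <- sample(letters, sample(3:15, 1))
    n_ab <- recovery_rate(a, b) * length(unique(a)) / 100
    n_ba <- recovery_rate(b, a) * length(unique(b)) / 100
    expect_equal(n_ab, length(intersect(a, b)))
    expect_equal(n_ab, n_ba)
  }
})

test_that("match_pair derives shared/exclusive sets and recoveries", {
  p <- match_pair(keyed(letters[1:5]), keyed(letters[1:5], "urine"), "P1")
  expect_equal(length(p$shared), 5L)
  expect_equal(length(p$plasma_exclusive), 0L)
  expect_equal(p$recovery_pu, 100)
  expect_equal(p$recovery_up, 100)

  q <- match_pair(keyed(letters[1:3]), keyed(letters[4:7], "urine"), "P2")
  expect_equal(length(q$shared), 0L)
  expect_equal(q$recovery_pu, 0)
  expect_equal(q$recovery_up, 0)

  r <- match_pair(keyed(paste0("k", 1:10)),
                  keyed(c(paste0("k", 1:4), paste0("u", 1:16)), "urine"), "P3")
  expect_equal(length(r$shared), 4L)
  expect_equal(r$recovery_pu, 40)
  expect_equal(r$recovery_up, 20)

  expect_error(match_pair(keyed(c("a", "a")), keyed("b", "urine")),
               "duplicate")
})

test_that("pathogenic recovery uses the source fluid's class only", {
  p <- match_pair(
    keyed(c("a", "b", "c"), class = c("pathogenic", "pathogenic", "VUS")),
    keyed(c("a", "x"), "urine", class = c("VUS", "pathogenic")), "P1")
  # a is pathogenic in plasma and present in urine (as VUS there): recovered
  expect_equal(p$path_recovery_pu, 50)
  # x is pathogenic in urine but absent from plasma
  expect_equal(p$path_recovery_up, 0)
})

test_that("cohort summary medians use the even-count convention", {
  mk <- function(pid, np, nu, fluid_keys = NULL) {
    pk <- paste0(pid, "p", seq_len(np))
    uk <- c(paste0(pid, "p", seq_len(min(np, 2))),
            paste0(pid, "u", seq_len(max(0, nu - min(np, 2)))))
    match_pair(keyed(pk, sample_id = pid),
               keyed(uk, "urine", sample_id = pid), pid)
  }
  pairs <- list(mk("A", 2, 6), mk("B", 4, 8))
  v <- rbind(keyed(paste0("A", 1:2), sample_id = "A"),
             keyed(paste0("B", 1:4), sample_id = "B"))
  v$vaf_bin <- "3-5"; v$tier <- "III"; v$gene <- "TP53"
  s <- cohort_summarize(pairs, v)
  expect_equal(s$medians$plasma_per_sample, 3)   # mean of {2, 4}
  expect_equal(s$medians$urine_per_sample, 7)
  expect_equal(s$venn$plasma_total, 6L)
  expect_equal(s$venn$urine_total, 14L)
})

test_that("Venn conservation and distribution sums hold on synthetic cohorts", {
  g <- cohort_fixture(3, 555)
  s <- g$res$summary
  expect_equal(s$venn$plasma_exclusive + s$venn$shared, s$venn$plasma_total)
  expect_equal(s$venn$urine_exclusive + s$venn$shared, s$venn$urine_total)
  expect_equal(s$venn$plasma_exclusive + s$venn$urine_exclusive +
                 2L * s$venn$shared, s$venn$grand_total)
  expect_equal(sum(s$per_sample$n_plasma), s$venn$plasma_total)
  for (tab in list(s$vaf_bins, s$class_dist, s$tier_dist)) {
    expect_equal(sum(tab$plasma), s$venn$plasma_total)
    expect_equal(sum(tab$urine), s$venn$urine_total)
  }
  expect_equal(sum(s$gene_table$total), s$venn$grand_total)
})

test_that("recovery medians are scale-free under patient duplication", {
  g <- cohort_fixture(3, 555)
  pairs <- g$res$pairs
  dup <- c(pairs, pairs)
  v <- g$res$survivors
  v2 <- rbind(v, transform(v, sample_id = paste0(sample_id, "dup")))
  s1 <- cohort_summarize(pairs, v)
  s2 <- cohort_summarize(dup, v2)
  expect_equal(s2$medians$recovery_pu, s1$medians$recovery_pu)
  expect_equal(s2$medians$recovery_up, s1$medians$recovery_up)
  expect_equal(s2$medians$plasma_per_sample, s1$medians$plasma_per_sample)
})

test_that("pathogenic matrix ranks ubiquitous variants first", {
  v <- rbind(
    keyed("g1", "plasma", "P1", "pathogenic"),
    keyed("g1", "urine", "P1", "pathogenic"),
    keyed("g1", "plasma", "P2", "pathogenic"),
    keyed("g1", "urine", "P2", "pathogenic"),
    keyed("g2", "plasma", "P1", "pathogenic"),
    keyed("g3", "urine", "P2", "VUS")
  )
  v$gene <- c("CHEK2", "CHEK2", "CHEK2", "CHEK2", "PTEN", "NF1")
  m <- pathogenic_matrix(v)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(rownames(m)[1], "CHEK2:g1")    # present in all 4 columns
  expect_equal(unname(rowSums(m)), c(4, 1))
  # no pathogenic variants -> empty matrix
  m0 <- pathogenic_matrix(keyed("a", class = "VUS"))
  expect_equal(nrow(m0), 0L)
})

test_that("planted presence pattern is reproduced exactly", {
  g <- cohort_fixture(3, 555)
  truth <- g$gen$truth
  surv <- truth[truth$fate == "survive" & truth$class_label == "pathogenic", ]
  m <- g$res$summary$pathogenic_matrix
  expect_equal(sum(m), nrow(surv))
  for (i in seq_len(min(nrow(surv), 50))) {
    col <- paste(surv$patient_id[i], surv$fluid[i], sep = "_")
    row <- paste(surv$gene[i], surv$key[i], sep = ":")
    expect_equal(m[row, col], 1L)
  }
})
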