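test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  k <- km_estimate(c(10, 20, 30, 40), rep(TRUE, 4))
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(k$median, 20)       # smallest t with S(t) <= 0.5
  # censoring-aware check against the oracle
  time <- c(5, 8, 8, 12, 20, 25)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  k2 <- km_estimate(time, event)
  orc <- km_oracle(time, event)
  expect_equal(k2$surv[match(orc$time, k2$time)], orc$surv)
  # S is non-increasing with S(0) = 1 implied
  expect_true(all(diff(k2$surv) <= 0))
  expect_true(all(k2$surv <= 1))
  # all censored: flat curve, undefined median
  k3 <- km_estimate(c(10, 20), c(FALSE, FALSE))
  expect_true(all(k3$surv == 1))
  expect_true(is.na(k3$median))
  # single event defines the median
  expect_equal(km_estimate(42, TRUE)$median, 42)
  expect_error(km_estimate(numeric(0), logical(0)), "no survival samples")
})

test_that("Gehan scores match the pairwise oracle, with censoring and ties", {
  set.seed(7)
  for (i in 1:20) {
    time <- sample(1:8, 9, replace = TRUE)
    event <- runif(9) < 0.7
    got <- ctcpheno:::gehan_scores(time, event)
    expect_equal(got, gehan_scores_oracle(time, event))
    expect_equal(sum(got), 0)   # scores always sum to zero
  }
})

test_that("Gehan test is symmetric and matches the permutation oracle", {
  a_t <- c(1, 2); a_e <- c(TRUE, TRUE)
  b_t <- c(10, 11); b_e <- c(TRUE, TRUE)
  g <- gehan_wilcoxon_test(a_t, a_e, b_t, b_e)
  expect_equal(g$statistic, 4)
  expect_equal(g$p_value, gehan_perm_oracle(a_t, a_e, b_t, b_e))
  expect_equal(g$p_value, 1 / 3)
  # identical multisets: W = 0, p = 1
  g0 <- gehan_wilcoxon_test(c(3, 9), c(TRUE, FALSE), c(3, 9), c(TRUE, FALSE))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
  # swapping strata negates W and leaves p unchanged
  set.seed(11)
  t1 <- rexp(5, 0.1); e1 <- runif(5) < 0.8
  t2 <- rexp(4, 0.3); e2 <- runif(4) < 0.8
  fwd <- gehan_wilcoxon_test(t1, e1, t2, e2)
  rev <- gehan_wilcoxon_test(t2, e2, t1, e1)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  # random small-sample agreement with the exhaustive oracle
  for (i in 1:10) {
    set.seed(300 + i)
    ta <- rexp(5, 0.1); ea <- runif(5) < 0.7
    tb <- rexp(5, 0.2); eb <- runif(5) < 0.7
    got <- gehan_wilcoxon_test(ta, ea, tb, eb)$p_value
    expect_equal(got, gehan_perm_oracle(ta, ea, tb, eb), tolerance = 1e-12)
  }
  expect_error(gehan_wilcoxon_test(numeric(0), logical(0), 1, TRUE),
               "nonempty")
})

test_that("without censoring Gehan reduces to the Wilcoxon rank-sum", {
  # W = -2 (U - n1 n2 / 2) for continuous, fully observed data
  for (i in 1:10) {
    set.seed(500 + i)
    a <- runif(4); b <- runif(4)
    w <- gehan_wilcoxon_test(a, rep(TRUE, 4), b, rep(TRUE, 4))$statistic
    u <- unname(wilcox.test(a, b)$statistic)
    expect_equal(w, -2 * (u - 8))
  }
})

test_that("stratification applies count, exclusivity and line filters", {
  counts <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    epithelial_ctc_count = c(0L, 0L, 2L, 0L),
    emt_ctc_count = c(3L, 1L, 1L, 0L),
    total_ctc_count = c(3L, 1L, 3L, 0L))
  clin <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                     treatment_line = c(2L, 2L, 3L, 1L),
                     pfs_days = c(40, 80, 100, 50),
                     pfs_event = TRUE,
                     os_days = c(100, 200, 300, 150),
                     os_event = TRUE)
  s <- stratify(counts, clin, "emt", min_count = 2, exclusive = TRUE)
  expect_equal(s$positive, "P1")
  expect_equal(sort(s$negative), c("P2", "P3"))   # P4 dropped by line filter
  # non-exclusive epithelial rule
  s2 <- stratify(counts, clin, "epithelial", min_count = 1)
  expect_equal(s2$positive, "P3")
  # no CTCs anywhere -> empty positive stratum
  counts0 <- counts; counts0[, 2:4] <- 0L
  expect_equal(length(stratify(counts0, clin, "emt", 1)$positive), 0)
  expect_error(stratify(rbind(counts, data.frame(
    patient_id = "PX", epithelial_ctc_count = 0L, emt_ctc_count = 0L,
    total_ctc_count = 0L)), clin, "emt"), "unknown patient")
})

test_that("strata recover the generator truth labels exactly", {
  sim <- generate_cohort(cohort_spec(n_patients = 60, seed = 23))
  qc <- qc_filter(sim$expr)
  # use true labels (not the classifier) to isolate the stratification op
  lab <- sim$cell_labels
  ann_true <- data.frame(
    cell_id = lab$cell_id,
    patient_id = sim$expr$cell_meta$patient_id,
    epithelial_group = ifelse(lab$archetype %in%
      c("epithelial_mid", "epithelial_high", "stem_cluster"), "Middle", "Low"),
    emt_stem_group = ifelse(lab$archetype %in% c("emt", "emt_mid"),
                            "LowStem_HighEMT", "LowStem_LowEMT"))
  counts <- patient_ctc_counts(ann_true, sim$clinical)
  expect_equal(counts$emt_ctc_count, sim$truth$emt_ctc_count)
  s <- stratify(counts, sim$clinical, "emt", min_count = 2,
                exclusive = FALSE, line_filter = 1)
  expect_setequal(s$positive, sim$truth$patient_id[sim$truth$emt_high])
})

test_that("survival report emits medians and flags degenerate strata", {
  clin <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                     treatment_line = 2L,
                     pfs_days = c(30, 35, 100, 120), pfs_event = TRUE,
                     os_days = c(90, 100, 300, 310), os_event = TRUE)
  counts <- data.frame(patient_id = clin$patient_id,
                       epithelial_ctc_count = 0L,
                       emt_ctc_count = c(2L, 3L, 0L, 0L),
                       total_ctc_count = c(2L, 3L, 0L, 0L))
  rules <- data.frame(ctc_type = "emt", min_count = 2L, exclusive = FALSE)
  rep <- survival_report(counts, clin, rules, line_filter = 2)
  expect_equal(nrow(rep), 4)    # 2 strata x 2 endpoints
  pfs_pos <- rep[rep$endpoint == "pfs" & rep$stratum == "positive", ]
  expect_equal(pfs_pos$median, 30)   # S(30) = 0.5 already

  expect_equal(pfs_pos$n, 2)
  # single-patient cohort: medians emitted, test not computable
  rep1 <- survival_report(counts[1, , drop = FALSE], clin[1, , drop = FALSE],
                          rules, line_filter = 2)
  expect_true(all(is.na(rep1$p_value)))
  expect_equal(rep1$median[rep1$stratum == "positive" &
                             rep1$endpoint == "pfs"], 30)
  # identical strata -> p = 1
  clin2 <- clin; clin2$pfs_days <- c(50, 60, 50, 60); clin2$os_days <- c(90, 95, 90, 95)
  rep2 <- survival_report(counts, clin2, rules, line_filter = 2)
  expect_true(all(rep2$p_value == 1))
})
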