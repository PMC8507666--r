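test_that("the reference 59-cell labels cross-tabulate to the published table", {
  ann <- reference_ctc_labels()
  tab <- cross_tabulate(ann)
  expect_identical(unname(tab), unname(table1_counts()))
  expect_equal(sum(tab), 59)
  # conservation on arbitrary annotations
  sim <- generate_cells(archetype_specs(), c(emt = 12, epithelial_mid = 7),
                        seed = 2)
  ann2 <- annotate_cells(sim$expr)
  expect_equal(sum(cross_tabulate(ann2)), nrow(ann2))
  # empty input gives the all-zero table
  empty <- cross_tabulate(ann[0, ])
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty), c(3, 4))
})

test_that("chi-square agrees with the direct-summation oracle", {
  tab <- table1_counts()
  got <- suppressWarnings(chi_square_test(tab))
  expect_equal(got$df, 6)
  expect_equal(got$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_warning(chi_square_test(tab), "expected count")

  # proportional table: statistic 0, p = 1
  prop <- outer(c(10, 20), c(5, 15, 30)) / 10
  got2 <- suppressWarnings(chi_square_test(prop))
  expect_equal(got2$statistic, 0)
  expect_equal(got2$p_value, 1)

  # degenerate margin
  bad <- matrix(c(1, 0, 2, 0), 2)
  expect_error(chi_square_test(bad), "degenerate margin")

  # transposition invariance
  r <- matrix(c(5, 2, 7, 9, 1, 4), 2)
  expect_equal(suppressWarnings(chi_square_test(r))$statistic,
               suppressWarnings(chi_square_test(t(r)))$statistic)
})

test_that("adjusted residuals reproduce the published significance grid", {
  tab <- table1_counts()
  res <- adjusted_residuals(tab)
  # Haberman formula spot check on the (High, HighStem) cell
  cell <- res[res$row == "High" & res$col == "HighStem_LowEMT", ]
  expect_equal(cell$expected, 8 * 7 / 59)
  expect_equal(cell$adjusted_residual, 7.1, tolerance = 0.01)
  expect_equal(cell$significance, "high_p01")
  # full signed pattern (rows High/Middle/Low x four EMT/stem columns)
  sig <- matrix(res$significance[order(match(res$row, rownames(tab)),
                                       match(res$col, colnames(tab)))],
                nrow = 3, byrow = TRUE)
  expect_equal(sig, matrix(c(
    "high_p01", "ns",       "ns",       "low_p01",
    "ns",       "ns",       "high_p01", "ns",
    "low_p01",  "high_p05", "low_p01",  "high_p01"), nrow = 3, byrow = TRUE))
  # independent cross-check against the stdres of chisq.test
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(matrix(res$adjusted_residual[order(match(res$row, rownames(tab)),
                                                  match(res$col, colnames(tab)))],
                      nrow = 3, byrow = TRUE),
               unname(ct$stdres), tolerance = 1e-12)
  # margins of O - E vanish exactly
  diff <- matrix(res$observed - res$expected, nrow = 3)
  expect_equal(rowSums(diff), rep(0, 3), tolerance = 1e-10)
  expect_equal(colSums(diff), rep(0, 4), tolerance = 1e-10)
})

test_that("significant-cell counting partitions the grid", {
  res <- adjusted_residuals(table1_counts())
  expect_equal(count_significant(res, "high", 0.05), 4)
  expect_equal(count_significant(res, "low", 0.05), 3)
  expect_equal(count_significant(res, "high", 0.01), 3)
  n_ns <- sum(res$significance == "ns")
  expect_equal(count_significant(res, "high", 0.05) +
                 count_significant(res, "low", 0.05) + n_ns, 12)
  prop <- outer(c(10, 20), c(5, 15, 30)) / 10
  res0 <- adjusted_residuals(prop)
  expect_true(all(res0$significance == "ns"))
  expect_equal(res0$adjusted_residual, rep(0, 6), tolerance = 1e-12)
})

test_that("category mapping covers exactly the four named pairs", {
  pairs <- data.frame(
    epithelial_group = c("High", "Low", "Middle", "Low", "High", "Low"),
    emt_stem_group = c("HighStem_LowEMT", "LowStem_MiddleEMT",
                       "LowStem_LowEMT", "LowStem_HighEMT",
                       "LowStem_HighEMT", "LowStem_LowEMT"))
  expect_equal(assign_categories(pairs),
               c("1", "2", "3", "4", "other", "other"))
})

test_that("detection rates follow the one-or-more rule over the full cohort", {
  ann <- reference_ctc_labels()
  clin <- data.frame(patient_id = reference_cohort_patients())
  det <- patient_positivity(ann, clin)
  expect_equal(det$positive, c(8, 20, 24))
  expect_equal(det$negative, c(19, 7, 3))
  expect_equal(det$rate_pct, c(30, 74, 89))
  # combined positives never fewer than either single type
  expect_gte(det$positive[3], max(det$positive[1:2]))
  # unknown patient in annotations
  bad <- ann; bad$patient_id[1] <- "NOPE"
  expect_error(patient_positivity(bad, clin), "absent from clinical")
})

test_that("fisher exact equals the enumeration oracle", {
  t1 <- matrix(c(8, 19, 20, 7), 2, byrow = TRUE)
  expect_lt(abs(fisher_exact_2x2(t1) - 0.0024), 5e-5)
  expect_equal(fisher_exact_2x2(t1), fisher_oracle(t1), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  # sweep of random tables with margins <= 30, plus stats::fisher.test
  set.seed(99)
  for (i in 1:50) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "empty")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("heterogeneity counts multi-category patients and pair fractions", {
  ann <- data.frame(
    patient_id = c("A", "A", "B", "C", "C"),
    category = c("2", "4", "3", "2", "4"))
  h <- heterogeneity_summary(ann)
  expect_equal(h$n_multi_category, 2)
  expect_equal(unname(h$combo_fractions["2+4"]), 1.0)
  # all single-category patients
  h0 <- heterogeneity_summary(data.frame(patient_id = c("A", "B"),
                                         category = c("1", "other")))
  expect_equal(h0$n_multi_category, 0)
  # brute-force distinct-category oracle on a random cohort
  set.seed(5)
  ann2 <- data.frame(patient_id = sample(LETTERS[1:8], 40, replace = TRUE),
                     category = sample(c("1", "2", "3", "4", "other"), 40,
                                       replace = TRUE))
  brute <- sum(vapply(split(ann2$category, ann2$patient_id),
                      function(x) length(unique(x)) >= 2, logical(1)))
  expect_equal(heterogeneity_summary(ann2)$n_multi_category, brute)
  # the reference cohort: 13 multi-category patients, 46% with the 2+4 pair
  h_ref <- heterogeneity_summary(reference_ctc_labels())
  expect_equal(h_ref$n_multi_category, 13)
  expect_equal(unname(h_ref$combo_fractions["2+4"]), 6 / 13)
})
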