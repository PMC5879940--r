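# ICC(2,1) against an independent ANOVA oracle, paired accuracy, and the
# table builders.

test_that("ICC(2,1) matches the from-scratch ANOVA oracle on random matrices", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:10, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 20, 4), n, k) +
      matrix(rep(rnorm(n, 0, 3), k), n, k) +      # subject effects
      matrix(rep(rnorm(k, 0, 1), each = n), n, k) # rater effects
    expect_equal(icc(m)$icc, icc21_aov_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC point estimate and CI match an external reference implementation", {
  # frozen oracle: pingouin 0.6.1 intraclass_corr, ICC(A,1) row, on this matrix
  m <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2), c(10, 5, 6), c(6, 2, 4))
  r <- icc(m)
  expect_equal(r$icc, 0.2235294118, tolerance = 1e-9)
  expect_equal(r$ci_low, -0.0088061255, tolerance = 1e-6)
  expect_equal(r$ci_high, 0.7109050608, tolerance = 1e-6)
  expect_equal(r$n_subjects, 6); expect_equal(r$n_raters, 3)
})

test_that("ICC edge cases: perfect agreement, pure noise, degenerate input", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc(m)$icc, 1)
  set.seed(42)
  noise <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(icc(noise)$icc), 0.05)
  expect_error(icc(matrix(3, 4, 2)), "zero total variance")
  expect_error(icc(matrix(1:4, 2, 2)[1, , drop = FALSE]), ">= 2")
  expect_error(icc(cbind(c(1, NA, 3), c(1, 2, 3))), "complete")
})

test_that("paired accuracy: identities, symmetry, and power on a shifted sample", {
  x <- c(10, 12, 14, 16, 18)
  same <- paired_accuracy(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_diff_vs_reference_deg, 0)
  set.seed(13)
  ref <- rnorm(71, 19.4, 3)
  shifted <- ref + 5 + rnorm(71, 0, 1)
  acc <- paired_accuracy(shifted, ref)
  expect_lt(acc$p_value, 0.001)
  expect_equal(acc$mean_diff_vs_reference_deg, mean(shifted - ref))
  flip <- paired_accuracy(ref, shifted)
  expect_equal(flip$t_statistic, -acc$t_statistic)
  expect_equal(flip$p_value, acc$p_value)
  expect_error(paired_accuracy(1:3, 1:4), "paired")
  # agreement with the standard paired t-test
  tt <- t.test(shifted, ref, paired = TRUE)
  expect_equal(acc$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(acc$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("intra-observer reliability uses exactly the two sessions per observer", {
  ds <- generate_cohort(cohort_config(n_patients = 6, seed = 14))
  m <- cupver:::record_matrix(ds$records, "lewinnek", by = "session", observer = 2)
  expect_equal(dim(m), c(6, 2))
  rel <- reliability_table(ds$records)
  expect_equal(nrow(rel), 7)
  expect_true(all(rel$intra_ci_low <= rel$icc_intra))
  expect_true(all(rel$icc_inter <= rel$inter_ci_high))
})

test_that("table builders mirror the study tables' structure", {
  ds <- generate_cohort(cohort_config(n_patients = 6, seed = 15))
  dir <- file.path(tempdir(), "tabs")
  tabs <- build_tables(ds, dir = dir)
  expect_equal(tabs$reliability$method[1], "reference")
  expect_equal(nrow(tabs$accuracy), 7)
  expect_true(is.na(tabs$accuracy$p_value[tabs$accuracy$method == "reference"]))
  expect_true(file.exists(file.path(dir, "table2_reliability.csv")))
  expect_true(file.exists(file.path(dir, "table3_accuracy.csv")))
  expect_true(file.exists(file.path(dir, "tables.md")))
  # write-then-read value identity
  rel2 <- utils::read.csv(file.path(dir, "table2_reliability.csv"))
  expect_equal(rel2$icc_intra, tabs$reliability$icc_intra)
  # missing-cell detection
  broken <- ds$records[!(ds$records$method == "hassan" & ds$records$observer == 2), ]
  expect_error(build_tables(broken), "missing cells")
  # single-method subset still analyzable alongside the reference
  sub <- ds$records[ds$records$method %in% c("reference", "liaw"), ]
  tabs2 <- build_tables(sub)
  expect_equal(nrow(tabs2$accuracy), 2)
  # no reference -> accuracy skipped with a warning
  noref <- ds$records[ds$records$method != "reference", ]
  expect_warning(t3 <- build_tables(noref), "reference")
  expect_null(t3$accuracy)
})

test_that("single-observer datasets drop the inter-observer row with a warning", {
  ds <- generate_cohort(cohort_config(n_patients = 5, n_observers = 1, seed = 16))
  expect_warning(rel <- reliability_table(ds$records), "single observer")
  expect_true(all(is.na(rel$icc_inter)))
  expect_false(anyNA(rel$icc_intra))
})

test_that("noise-free cohort: AP ellipse methods identical to reference, biased methods flagged", {
  cfg <- cohort_config(n_patients = 10, landmark_sd_mm = 0, observer_bias_mm = 0,
                       n_observers = 1, n_sessions_intra = 1, seed = 17)
  ds <- generate_cohort(cfg)
  acc <- accuracy_table(ds$records)
  rownames(acc) <- acc$method
  for (m in c("liaw", "lewinnek", "hassan", "ackland")) {
    expect_lt(abs(acc[m, "mean_diff_vs_reference_deg"]), 1e-4)
  }
  expect_lt(acc["widmer", "p_value"], 0.05)
  expect_lt(acc["woo_morrey", "p_value"], 0.05)
  expect_gt(acc["widmer", "mean_diff_vs_reference_deg"], 0)
  expect_gt(acc["woo_morrey", "mean_diff_vs_reference_deg"], 0)
})
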