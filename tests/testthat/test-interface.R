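# Reading, pairing, the end-to-end pipeline and its report files.

tiny_long <- function() {
  data.frame(
    participant = rep(c("A", "B", "C"), each = 2),
    session = rep(1:2, 3),
    task = "T1", parameter = "p1",
    value = c(0.1, 0.2, -0.5, -0.4, 1.0, 1.1)
  )
}

test_that("assessment tables are validated on read", {
  df <- tiny_long()
  expect_identical(read_assessments(df)$value, df$value)
  dup <- rbind(df, df[1, ])
  expect_error(read_assessments(dup), "duplicate")
  bad <- df
  bad$session[1] <- 3
  expect_error(read_assessments(bad), "coded 1 and 2")
  expect_error(read_assessments(df[, -5]), "missing column")
})

test_that("pairing drops and counts participants missing a session", {
  df <- tiny_long()
  p <- pair_observations(df)
  expect_identical(length(p$pairs$p1$session1), 3L)
  expect_identical(unname(p$n_excluded["p1"]), 0L)
  # remove C's second session
  p2 <- pair_observations(df[-6, ])
  expect_identical(p2$pairs$p1$participant_ids, c("A", "B"))
  expect_identical(unname(p2$n_excluded["p1"]), 1L)
})

test_that("the pipeline writes the full report with the expected schema", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report")
  sim <- simulate_assessments(sim_config(n_participants = 30,
                                         outlier_rate = 0, seed = 71L))
  fit <- run_retest_pipeline(sim$assessments, trials = sim$trials,
                             output_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "results_full.csv", "results_rounded.csv", "cumulative_ci.csv",
    "cumulative_learning.csv", "cumulative_icc.csv", "manifest.txt")))))
  res <- utils::read.csv(file.path(out, "results_full.csv"))
  expect_true(all(c("parameter", "task", "n_pairs", "n_outliers_removed",
                    "sd_diff", "ci", "sc", "icc_c", "mean_diff", "p_value",
                    "q_value", "significant_raw", "significant_fdr",
                    "pooled_sem", "is_error") %in% names(res)))
  # nothing was injected, and Normal difference scores essentially never
  # exceed the 3.2 threshold at these sizes
  expect_true(all(res$n_outliers_removed == 0))
  # trial-bearing parameters (and only those) carry an IS-error column
  has_trials <- res$parameter %in% unique(sim$trials$parameter)
  expect_true(all(is.finite(res$is_error[has_trials])))
  expect_true(all(is.na(res$is_error[!has_trials])))
  manifest <- readLines(file.path(out, "manifest.txt"))
  expect_true(any(grepl("ci_multiplier = 1.64", manifest, fixed = TRUE)))
})

test_that("re-running the pipeline reproduces byte-identical reports", {
  dir <- withr::local_tempdir()
  sim <- simulate_assessments(sim_config(n_participants = 25, seed = 72L))
  run_retest_pipeline(sim$assessments, output_dir = file.path(dir, "r1"))
  run_retest_pipeline(sim$assessments, output_dir = file.path(dir, "r2"))
  for (f in list.files(file.path(dir, "r1"))) {
    expect_identical(readLines(file.path(dir, "r1", f)),
                     readLines(file.path(dir, "r2", f)))
  }
})

test_that("a failing stage aborts with a labelled error and no partial output", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report")
  bad <- tiny_long()[1:2, ]  # a single pair cannot support the analysis
  expect_error(run_retest_pipeline(bad, output_dir = out),
               "pipeline failed at stage 'fit'")
  expect_true(!dir.exists(out) || length(list.files(out)) == 0L)
})

test_that("end-to-end estimates recover the generating components", {
  sim <- simulate_assessments(sim_config(seed = 73L))
  fit <- retest_reliability(sim$assessments)
  res <- fit$results
  truth <- sim$truth
  # averaging across the 33 parameters tightens each estimate
  expect_equal(mean(res$sd_diff), truth$expected_sd_diff, tolerance = 0.05)
  expect_equal(mean(res$ci), 1.64 * truth$expected_sd_diff,
               tolerance = 0.05)
  expect_equal(mean(res$icc_c), truth$expected_icc, tolerance = 0.1)
  expect_equal(mean(res$mean_diff), truth$learning_shift, tolerance = 0.3)
  # exclusion counts reconcile with the input
  expect_identical(res$n_pairs + res$n_outliers_removed,
                   rep(sim$config$n_participants, nrow(res)))
})

test_that("the published task-score summary is internally consistent", {
  ref <- kst_reference_summary()
  expect_identical(nrow(ref), 11L)
  # printed SC column equals sqrt(2) * printed CI up to rounding
  expect_lt(max(abs(ref$significant_change -
                    sqrt(2) * ref$confidence_interval)), 0.01)
  expect_identical(sum(ref$outliers_removed), 2L)
})
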