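# Paired learning-effect tests and family-wide FDR control.

test_that("paired t-test matches hand computation and handles edges", {
  r <- paired_t_learning(c(0, 0, 0), c(1, 2, 3))
  expect_identical(r$mean_diff, 2)
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  same <- paired_t_learning(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$mean_diff, 0)
  expect_identical(same$p_value, 1)

  const <- paired_t_learning(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_identical(const$mean_diff, 0.5)
  expect_identical(const$p_value, .Machine$double.xmin)

  expect_error(paired_t_learning(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("the paired test keeps its nominal type-I error under the null", {
  set.seed(27)
  n_rep <- 5000
  p <- vapply(seq_len(n_rep), function(i) {
    d <- rnorm(20)
    paired_t_learning(rep(0, 20), d)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("BH agrees with the exhaustive-threshold oracle", {
  expect_identical(benjamini_hochberg(numeric(0))$q_values, numeric(0))
  r4 <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(r4$q_values, rep(0.04, 4))
  expect_true(all(r4$reject))
  r1 <- benjamini_hochberg(0.04, 0.05)
  expect_equal(r1$q_values, 0.04)
  expect_true(r1$reject)
  r0 <- benjamini_hochberg(c(0.5, 0.6, 0.9), 0.05)
  expect_false(any(r0$reject))

  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    got <- benjamini_hochberg(p, 0.05)
    want <- bh_oracle(p, 0.05)
    expect_equal(got$q_values, want$q_values, tolerance = 1e-12)
    expect_identical(got$reject, want$reject)
    # q-values are monotone in p and never below p
    ord <- order(p)
    expect_true(all(diff(got$q_values[ord]) >= -1e-15))
    expect_true(all(got$q_values >= p - 1e-15))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the learning-effect table corrects across the whole family", {
  set.seed(35)
  n <- 30
  s <- rnorm(n)
  pairs <- list(
    a = make_pairs(s, s + rnorm(n, -1, 0.3), "a", "T1"),
    b = make_pairs(s, s + rnorm(n, 0, 0.3), "b", "T1"),
    c = make_pairs(s, s + rnorm(n, 0, 0.3), "c", "T2")
  )
  tab <- learning_effect_table(pairs)
  expect_identical(tab$parameter, c("a", "b", "c"))
  expect_true(all(tab$q_value >= tab$p_value))
  expect_true(all(tab$significant_fdr <= tab$significant_raw))
  expect_true(tab$significant_fdr[1])

  single <- learning_effect_table(pairs["a"])
  expect_identical(single$q_value, single$p_value)

  per_task <- learning_effect_table(pairs, fdr_family = "task")
  # parameter c is alone in its task, so its q collapses to its p there
  expect_identical(per_task$q_value[3], per_task$p_value[3])
})

test_that("battery-wide FDR holds with many null and some shifted parameters", {
  # 150 null + 17 shifted parameters, 56 pairs, SD_diff = sqrt(2) * 0.7
  set.seed(37)
  n <- 56
  shift <- c(rep(0, 150), rep(-0.8, 17))
  n_rep <- 20
  fdp <- power <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pairs <- lapply(seq_along(shift), function(k) {
      make_pairs(rep(0, n), rnorm(n, shift[k], sqrt(2) * 0.7),
                 parameter = paste0("p", k))
    })
    tab <- learning_effect_table(pairs)
    disc <- which(tab$significant_fdr)
    fdp[r] <- if (length(disc)) mean(disc <= 150) else 0
    power[r] <- mean(tab$significant_fdr[151:167])
  }
  expect_lt(mean(fdp), 0.08)     # target FDR 0.05 * 150/167
  expect_gt(mean(power), 0.9)

  # an all-null family yields almost no discoveries
  set.seed(38)
  null_rejections <- vapply(1:40, function(r) {
    p <- vapply(1:167, function(k) {
      paired_t_learning(rep(0, 15), rnorm(15))$p_value
    }, numeric(1))
    sum(benjamini_hochberg(p, 0.05)$reject)
  }, numeric(1))
  expect_lt(mean(null_rejections), 0.5)
})

test_that("a strong practice effect is detected with near-certain power", {
  # shift -0.78 against the reaction-time difference spread (CI 0.95)
  set.seed(39)
  sd_diff <- 0.95 / 1.64
  hits <- vapply(1:200, function(i) {
    paired_t_learning(rep(0, 56), rnorm(56, -0.78, sd_diff))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
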