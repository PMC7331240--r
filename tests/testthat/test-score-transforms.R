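# The Zeta / Task-Score transform stack and the iterative normalization.

test_that("folding transforms match the quantile-form oracle", {
  # the naive quantile form is itself double-precision-accurate up to z ~ 4;
  # past that the defining relation Phi(-zeta) = Phi(-z)/2 is the stable check
  z <- seq(-6, 4, by = 0.01)
  expect_lt(max(abs(zeta_transform(z) - quantile_fold_oracle(z))), 1e-10)
  expect_lt(max(abs(task_score(z) - quantile_fold_oracle(z))), 1e-10)
  tail <- seq(4, 6, by = 0.01)
  expect_lt(max(abs(pnorm(-zeta_transform(tail)) / (pnorm(-tail) / 2) - 1)),
            1e-12)
  # frozen landmarks: median performance and the impairment threshold
  expect_equal(zeta_transform(0), qnorm(0.75), tolerance = 1e-12)
  expect_equal(round(zeta_transform(0), 4), 0.6745)
  expect_equal(zeta_transform(1.64), quantile_fold_oracle(1.64),
               tolerance = 1e-12)
  expect_equal(round(zeta_transform(1.64), 3), 1.956)
  # strictly increasing, with a lower asymptote at 0
  zz <- seq(-6, 6, by = 0.01)
  expect_true(all(diff(zeta_transform(zz)) > 0))
  expect_lt(zeta_transform(-8), 1e-8)
  expect_gt(zeta_transform(-8), 0)
  expect_error(zeta_transform(c(0, NA)), "finite")
  expect_error(task_score(Inf), "finite")
})

test_that("rss distance is the Euclidean norm over present components", {
  expect_equal(rss_distance(c(3, 4), numeric(0)), 5)
  expect_equal(rss_distance(c(1, 2), 2), 3)
  expect_equal(rss_distance(rep(0, 5), rep(0, 3)), 0)
  # missing components are dropped, not imputed
  expect_equal(rss_distance(c(3, NA), 4), 5)
  expect_error(rss_distance(NA_real_, NA_real_), "finite")
  # exact agreement with a naive loop on random vectors
  set.seed(11)
  for (i in 1:20) {
    z <- rnorm(sample(1:6, 1))
    zeta <- abs(rnorm(sample(0:4, 1)))
    acc <- 0
    for (v in c(z, zeta)) acc <- acc + v * v
    expect_equal(rss_distance(z, zeta)^2, acc, tolerance = 1e-14)
  }
})

test_that("mahalanobis distance matches a hand-inverted 2x2 oracle", {
  # identity covariance reduces to the RSS distance
  set.seed(4)
  z <- rnorm(4)
  expect_equal(mahalanobis_distance(z, diag(4)), rss_distance(z),
               tolerance = 1e-6)
  expect_equal(mahalanobis_distance(c(0, 0, 0), diag(3)), 0)
  # correlation 0.5: Sigma^-1 = [[1, -.5], [-.5, 1]] / 0.75
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mahalanobis_distance(c(1, 1), sigma),
               sqrt((1 - 0.5 - 0.5 + 1) / 0.75), tolerance = 1e-6)
  expect_error(mahalanobis_distance(c(1, 1, 1), sigma), "square")
  # ridge keeps singular covariances usable
  expect_true(is.finite(
    mahalanobis_distance(c(1, 1), matrix(1, 2, 2))))
})

test_that("normalization trims gross outliers and de-skews", {
  set.seed(21)
  x <- c(rnorm(10000), 8)
  m <- fit_normalization(x)
  expect_gte(m$n_outliers_trimmed, 1L)
  expect_equal(mean(m$retained), 0, tolerance = 1e-8)
  expect_equal(sd(m$retained), 1, tolerance = 1e-8)
  # the injected point standardizes far beyond the trimming threshold
  expect_gt(predict(m, 8), 3.29)

  # log-normal data: lambda near the log limit, skewness removed
  set.seed(22)
  ln <- exp(rnorm(10000))
  ml <- fit_normalization(ln)
  expect_lt(abs(ml$box_cox_lambda), 0.15)
  expect_lt(abs(sample_skewness(ml$retained)), 0.1)

  # already-Normal data: lambda in the identity region, ~0.1% trimmed
  set.seed(23)
  nn <- rnorm(10000)
  mn <- fit_normalization(nn)
  expect_lt(mn$n_outliers_trimmed / 10000, 0.005)

  expect_error(fit_normalization(rnorm(5)), "at least 10")
  expect_error(fit_normalization(rep(2, 50)), "degenerate")
})

test_that("normalization is idempotent in effect and serializes", {
  set.seed(31)
  x <- exp(rnorm(2000))
  m <- fit_normalization(x)
  z <- m$retained
  # refit on its own standardized output: nothing substantive changes
  m2 <- fit_normalization(z)
  expect_lte(m2$n_outliers_trimmed, 2L)
  z2 <- predict(m2, z)
  expect_equal(mean(z2, na.rm = TRUE), 0, tolerance = 1e-6)
  expect_gt(cor(z, z2, use = "complete.obs"), 0.9999)

  # key-value round trip reproduces predictions exactly
  path <- withr::local_tempfile(fileext = ".txt")
  write_normalization_model(m, path)
  m3 <- read_normalization_model(path)
  new <- c(0.5, 1, 2, 5)
  expect_identical(predict(m, new), predict(m3, new))
})

test_that("z_task_score centres the reference distribution", {
  set.seed(41)
  # chi-distributed composite distances, as RSS over 4 parameters gives
  ref <- sqrt(rowSums(matrix(rnorm(4e4), ncol = 4)^2))
  expect_lt(abs(z_task_score(ref, median(ref))), 0.05)
  expect_gt(z_task_score(ref, max(ref) * 1.5), 0)
  expect_lt(z_task_score(ref, min(ref) / 2), 0)
})

test_that("task-score confidence bounds are asymmetric and approach the CI", {
  # worked case: z = 0, ci = 1
  tc <- task_score_ci(0, 1)
  expect_equal(tc$upper_bound - tc$task_score,
               quantile_fold_oracle(1) - quantile_fold_oracle(0),
               tolerance = 1e-12)
  expect_equal(round(tc$upper_bound - tc$task_score, 3), 0.735)
  expect_equal(round(tc$task_score - tc$lower_bound, 3), 0.474)

  grid <- task_score_ci(seq(-4, 4, by = 0.1), 1)
  up <- grid$upper_bound - grid$task_score
  lo <- grid$task_score - grid$lower_bound
  expect_true(all(grid$lower_bound >= 0))
  expect_true(all(grid$lower_bound <= grid$task_score))
  expect_true(all(grid$task_score <= grid$upper_bound))
  expect_true(all(up >= lo))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(lo) > 0))
  expect_true(all(up < 1))
  expect_true(all(lo < 1))
  # far in the impaired tail both distances converge to the CI width
  far <- task_score_ci(10, 1)
  expect_equal(far$upper_bound - far$task_score, 1, tolerance = 0.05)
  expect_equal(far$task_score - far$lower_bound, 1, tolerance = 0.05)

  expect_error(task_score_ci(0, -1), "positive")
  expect_error(task_score_ci(0, 0), "positive")
})
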