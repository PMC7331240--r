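# Monte Carlo studies: estimator stability versus sample size, and the
# asymmetry of Task-Score confidence intervals.

#' Monte Carlo stability of the sample mean and SD versus sample size
#'
#' For each grid size n, draws n standard-Normal values and records the
#' sample mean and sample SD; repeats `n_iterations` times and reports the
#' variance of the recorded means and of the recorded SDs. The analytic
#' references are `1/n` for the mean and approximately `1/(2n)` for the
#' SD, so both curves shrink toward 0 and flatten — the basis for choosing
#' a minimum cohort size (around 50, where the variance of the mean is
#' within +/-0.02).
#'
#' Each grid point uses an independent RNG stream derived from the master
#' seed, so curves are reproducible point-wise regardless of grid order.
#'
#' @param n_grid integer sample sizes, all >= 2 (default `5:100`).
#' @param n_iterations Monte Carlo replicates per grid point (default
#'   10000, minimum 100).
#' @param seed master RNG seed.
#' @return a data frame of class `"sample_size_curve"` with columns `n`,
#'   `var_of_mean`, `var_of_sd`; `n_iterations` and `seed` are attached as
#'   attributes.
#' @export
sample_size_simulation <- function(n_grid = 5:100, n_iterations = 10000,
                                   seed = 1L) {
  n_grid <- as.integer(n_grid)
  if (length(n_grid) == 0L || any(n_grid < 2L)) {
    stop("all grid sizes must be >= 2", call. = FALSE)
  }
  if (n_iterations < 100L) {
    stop("`n_iterations` must be at least 100", call. = FALSE)
  }
  seed <- as.integer(seed)
  res <- vapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    # per-point substream, kept inside 32-bit integer range
    set.seed((abs(seed) * 1009L + n) %% .Machine$integer.max)
    x <- matrix(stats::rnorm(n * n_iterations), nrow = n)
    means <- colMeans(x)
    sds <- sqrt((colSums(x^2) - n * means^2) / (n - 1))
    c(stats::var(means), stats::var(sds))
  }, numeric(2))
  out <- data.frame(n = n_grid, var_of_mean = res[1, ], var_of_sd = res[2, ])
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- seed
  class(out) <- c("sample_size_curve", "data.frame")
  out
}

#' Simulated distribution of Task Scores and their asymmetric bounds
#'
#' Draws n standard-Normal Z-Task Scores, converts each to a one-sided
#' Task Score with confidence bounds via [task_score_ci()], and summarizes
#' the resulting distribution: the empirical CDF of Task Scores (a Task
#' Score of 1 covers ~68.3% of the population, mirroring the +/-1 band of
#' the Z scale) and the upper/lower bound distances, which approach `ci`
#' for large scores.
#'
#' @param n number of simulated scores (>= 100; default 10000).
#' @param ci half-width of the Z-scale confidence interval (default 1).
#' @param seed RNG seed.
#' @return list with `scores` (a [task_score_ci()] data frame augmented
#'   with `lower_distance` and `upper_distance`), `ecdf` (the empirical
#'   CDF function of the Task Scores), `fraction_below_1`, and `ci`.
#' @export
task_score_ci_simulation <- function(n = 10000, ci = 1, seed = 1L) {
  if (n < 100L) stop("`n` must be at least 100", call. = FALSE)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  scores <- task_score_ci(z, ci)
  scores$lower_distance <- scores$task_score - scores$lower_bound
  scores$upper_distance <- scores$upper_bound - scores$task_score
  list(scores = scores,
       ecdf = stats::ecdf(scores$task_score),
       fraction_below_1 = mean(scores$task_score <= 1),
       ci = ci)
}
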