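# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# quantile form of the one-sided folding transform
quantile_fold_oracle <- function(z) qnorm((1 + pnorm(z)) / 2)

# brute-force two-way crossed (subjects x sessions) mean squares, explicit
# loops over cell means
anova_ms_oracle <- function(s1, s2) {
  x <- cbind(s1, s2)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  subj_means <- rowMeans(x)
  sess_means <- colMeans(x)
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (subj_means[i] - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_err <- ss_err +
        (x[i, j] - subj_means[i] - sess_means[j] + grand)^2
    }
  }
  list(ms_subjects = unname(ss_subj) / (n - 1),
       ms_error = unname(ss_err) / ((n - 1) * (k - 1)))
}

# exhaustive Benjamini-Hochberg: checks every candidate rejection threshold
# and computes q-values as the explicit minimum over larger ranks
bh_oracle <- function(p, level) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  largest <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * level / m) largest <- i
  reject_sorted <- seq_len(m) <= largest
  q_sorted <- numeric(m)
  for (i in seq_len(m)) q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  reject <- logical(m)
  reject[ord] <- reject_sorted
  list(q_values = q, reject = reject)
}

# paired dataset with a single parameter, convenient for estimator checks
make_pairs <- function(s1, s2, parameter = "p", task = "t") {
  paired_observations(seq_along(s1), s1, s2, parameter, task)
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / sd(x)
  mean(z^3)
}
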