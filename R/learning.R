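# Learning effects: paired t-tests on session differences, corrected for
# the false discovery rate across the whole parameter family.

#' Paired t-test for a first-to-second-session shift
#'
#' Two-sided paired t-test on the difference scores
#' `d = session2 - session1`. Negative mean differences indicate lower
#' (better) Z-scores at retest, i.e. a practice benefit. Degenerate inputs
#' are handled explicitly: if every difference is zero the shift is 0 with
#' p = 1; if the differences are constant but nonzero the evidence is
#' unbounded and p is the smallest representable double.
#'
#' @param session1,session2 aligned numeric vectors, at least 3 pairs.
#' @return list with `mean_diff`, `t_statistic`, `df`, `p_value`.
#' @examples
#' paired_t_learning(c(0, 0, 0), c(1, 2, 3))  # t = 2 * sqrt(3)
#' @export
paired_t_learning <- function(session1, session2) {
  if (length(session1) != length(session2)) {
    stop("sessions must have equal length", call. = FALSE)
  }
  keep <- is.finite(session1) & is.finite(session2)
  d <- session2[keep] - session1[keep]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  m <- mean(d)
  if (stats::sd(d) == 0) {
    if (m == 0) {
      return(list(mean_diff = 0, t_statistic = 0, df = n - 1L, p_value = 1))
    }
    return(list(mean_diff = m, t_statistic = sign(m) * Inf, df = n - 1L,
                p_value = .Machine$double.xmin))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(mean_diff = m, t_statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure over a family of p-values: sort ascending, find the
#' largest rank i with `p_(i) <= i * fdr_level / m`, and reject that and
#' all smaller ranks. The q-values are the monotone-adjusted `p * m / rank`
#' values capped at 1; a hypothesis is rejected exactly when its q-value is
#' at most `fdr_level`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param fdr_level target false discovery rate (default 0.05).
#' @return list with `q_values` and logical `reject` flags, in input order.
#' @export
benjamini_hochberg <- function(p_values, fdr_level = 0.05) {
  if (length(p_values) == 0L) {
    return(list(q_values = numeric(0), reject = logical(0)))
  }
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= fdr_level)
}

#' Learning-effect table across all parameters
#'
#' Runs [paired_t_learning()] on the outlier-excluded difference scores of
#' each parameter, then applies [benjamini_hochberg()] across the family.
#' By default the family is all parameters of all tasks in the run (the
#' battery-wide correction); `fdr_family = "task"` corrects within each
#' task separately.
#'
#' @param pairs_list list of [paired_observations()] (typically with
#'   difference outliers already flagged).
#' @param config a [threshold_config()]; `alpha` is both the raw
#'   significance level and the FDR level.
#' @param fdr_family `"all"` (default) or `"task"`.
#' @return data frame with one row per parameter: `parameter`, `task`,
#'   `n_pairs`, `mean_diff`, `t_statistic`, `df`, `p_value`, `q_value`,
#'   `significant_raw`, `significant_fdr`.
#' @export
learning_effect_table <- function(pairs_list, config = threshold_config(),
                                  fdr_family = c("all", "task")) {
  fdr_family <- match.arg(fdr_family)
  if (length(pairs_list) == 0L) stop("no parameters supplied", call. = FALSE)
  rows <- lapply(pairs_list, function(pr) {
    u <- unflagged_(pr)
    res <- paired_t_learning(u$s1, u$s2)
    data.frame(parameter = pr$parameter, task = pr$task,
               n_pairs = length(u$s1), mean_diff = res$mean_diff,
               t_statistic = res$t_statistic, df = res$df,
               p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  if (fdr_family == "all") {
    out$q_value <- benjamini_hochberg(out$p_value, config$alpha)$q_values
  } else {
    for (tk in unique(out$task)) {
      idx <- out$task == tk
      out$q_value[idx] <-
        benjamini_hochberg(out$p_value[idx], config$alpha)$q_values
    }
  }
  out$significant_raw <- out$p_value < config$alpha
  out$significant_fdr <- out$q_value <= config$alpha
  out
}
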