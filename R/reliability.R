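# Retest reliability per parameter: difference-score outliers, SD_diff,
# confidence interval, significant-change threshold, and consistency ICC.

#' Analysis thresholds and options
#'
#' @param ci_multiplier width of the retest confidence interval in SDs of
#'   the difference score (default 1.64, the one-tailed 90% / two-region
#'   5-95% bound; use 1.96 for a fully two-tailed interval).
#' @param diff_outlier_threshold difference scores with
#'   `|session2 - session1|` strictly greater than this are excluded
#'   (default 3.2, roughly a 1-in-1000 event for standard-Normal scores).
#' @param z_outlier_threshold trimming threshold for the normalization loop
#'   (default 3.29, the two-sided 0.001 tail).
#' @param alpha significance level of the paired learning-effect test and
#'   the FDR level (default 0.05).
#' @param icc_formula `"variance_components"` (default) computes the
#'   consistency ICC as `(MS_S - MS_E) / (MS_S + MS_E)`, the two-session
#'   ICC(C,1) that equals the between-subject share of variance;
#'   `"literal_ms_ratio"` computes `MS_S / (MS_S + MS_E)`, a variant that
#'   returns 0.5 rather than 0 when subjects do not differ, retained for
#'   fidelity comparisons.
#' @return a `"threshold_config"` list.
#' @export
threshold_config <- function(ci_multiplier = 1.64,
                             diff_outlier_threshold = 3.2,
                             z_outlier_threshold = 3.29,
                             alpha = 0.05,
                             icc_formula = c("variance_components",
                                             "literal_ms_ratio")) {
  icc_formula <- match.arg(icc_formula)
  thr <- c(ci_multiplier, diff_outlier_threshold, z_outlier_threshold)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("all thresholds must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(list(ci_multiplier = ci_multiplier,
                 diff_outlier_threshold = diff_outlier_threshold,
                 z_outlier_threshold = z_outlier_threshold,
                 alpha = alpha, icc_formula = icc_formula),
            class = "threshold_config")
}

#' Aligned session-1 / session-2 observations for one parameter
#'
#' @param participant_ids vector of participant identifiers.
#' @param session1,session2 numeric vectors of the two assessments, aligned
#'   with `participant_ids`.
#' @param parameter optional parameter name.
#' @param task optional task name.
#' @return a `"paired_observations"` list with difference-outlier flags
#'   initialized to `FALSE`.
#' @export
paired_observations <- function(participant_ids, session1, session2,
                                parameter = NA_character_,
                                task = NA_character_) {
  n <- length(participant_ids)
  if (length(session1) != n || length(session2) != n) {
    stop("sessions and participant ids must have equal length",
         call. = FALSE)
  }
  structure(list(participant_ids = participant_ids,
                 session1 = as.numeric(session1),
                 session2 = as.numeric(session2),
                 diff_outlier_flags = rep(FALSE, n),
                 parameter = parameter, task = task),
            class = "paired_observations")
}

#' Flag implausibly large retest differences as outliers
#'
#' Marks pairs whose difference score `session2 - session1` exceeds the
#' threshold in absolute value (strictly: a difference equal to the
#' threshold is retained). Flagged pairs are excluded from all downstream
#' SD_diff, CI/SC, ICC and learning-effect computation, and their count is
#' carried into the results.
#'
#' @param pairs a [paired_observations()].
#' @param threshold flagging threshold on `|d|` (default 3.2).
#' @return `pairs` with `diff_outlier_flags` set.
#' @export
flag_difference_outliers <- function(pairs, threshold = 3.2) {
  stopifnot(inherits(pairs, "paired_observations"))
  if (length(pairs$session1) < 2L) {
    stop("need at least 2 pairs", call. = FALSE)
  }
  d <- pairs$session2 - pairs$session1
  pairs$diff_outlier_flags <- is.finite(d) & abs(d) > threshold
  pairs
}

unflagged_ <- function(pairs) {
  keep <- !pairs$diff_outlier_flags &
    is.finite(pairs$session1) & is.finite(pairs$session2)
  list(s1 = pairs$session1[keep], s2 = pairs$session2[keep],
       n_removed = sum(pairs$diff_outlier_flags))
}

#' Retest confidence interval and significant-change threshold
#'
#' From the unflagged difference scores `d = session2 - session1`:
#' `SD_diff` is the sample SD (n - 1 denominator), the assessment
#' confidence interval is `CI = ci_multiplier * SD_diff` (default 1.64,
#' so only ~5% of stable participants change by more than CI in a given
#' direction), and the significant-change threshold is `SC = sqrt(2) * CI`.
#'
#' @param pairs a [paired_observations()] (flag outliers first with
#'   [flag_difference_outliers()]).
#' @param config a [threshold_config()].
#' @return list with `n_pairs`, `n_outliers_removed`, `sd_diff`, `ci`, `sc`.
#' @examples
#' p <- paired_observations(1:3, c(0, 0, 0), c(-1, 0, 1))
#' compute_ci_sc(p)  # sd_diff = 1, ci = 1.64, sc = 2.3192
#' @export
compute_ci_sc <- function(pairs, config = threshold_config()) {
  stopifnot(inherits(pairs, "paired_observations"))
  u <- unflagged_(pairs)
  if (length(u$s1) < 2L) {
    stop("need at least 2 unflagged pairs", call. = FALSE)
  }
  sd_diff <- stats::sd(u$s2 - u$s1)
  ci <- config$ci_multiplier * sd_diff
  list(n_pairs = length(u$s1), n_outliers_removed = u$n_removed,
       sd_diff = sd_diff, ci = ci, sc = sqrt(2) * ci)
}

#' Significant-change threshold from a confidence interval
#'
#' `SC = sqrt(2) * CI`: the factor sqrt(2) reflects that a change score
#' compounds the measurement error of two assessments.
#'
#' @param ci assessment confidence interval (non-negative).
#' @return non-negative numeric vector.
#' @examples
#' significant_change(0.95)  # 1.34 to 2 d.p.
#' @export
significant_change <- function(ci) {
  if (any(ci < 0, na.rm = TRUE)) stop("`ci` must be >= 0", call. = FALSE)
  sqrt(2) * ci
}

# two-way crossed (subjects x sessions) mean squares via stats::aov
anova_ms_ <- function(s1, s2) {
  n <- length(s1)
  d <- data.frame(
    value = c(s1, s2),
    subject = factor(rep(seq_len(n), 2L)),
    session = factor(rep(1:2, each = n))
  )
  fit <- stats::aov(value ~ subject + session, data = d)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  list(ms_subjects = ms[["subject"]], ms_error = ms[["Residuals"]])
}

#' Consistency intraclass correlation across two assessments
#'
#' Two-way crossed decomposition (subjects x sessions) of the unflagged
#' pairs; the session main effect absorbs any systematic shift (learning),
#' so the consistency ICC ignores it — by design, since learning effects
#' are tested explicitly elsewhere. With `MS_S` the between-subject mean
#' square and `MS_E` the residual mean square, the default
#' `"variance_components"` formula returns `(MS_S - MS_E) / (MS_S + MS_E)`
#' (the k = 2 consistency ICC, estimating
#' `sigma_subject^2 / (sigma_subject^2 + sigma_error^2)`);
#' `"literal_ms_ratio"` returns `MS_S / (MS_S + MS_E)`.
#'
#' @param pairs a [paired_observations()] with outliers flagged.
#' @param formula which estimator to use; see [threshold_config()].
#' @return list with `icc_c`, `ms_subjects`, `ms_error`.
#' @export
icc_consistency <- function(pairs,
                            formula = c("variance_components",
                                        "literal_ms_ratio")) {
  stopifnot(inherits(pairs, "paired_observations"))
  formula <- match.arg(formula)
  u <- unflagged_(pairs)
  if (length(u$s1) < 3L) {
    stop("need at least 3 unflagged pairs", call. = FALSE)
  }
  if (stats::var(c(u$s1, u$s2)) == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  ms <- anova_ms_(u$s1, u$s2)
  icc <- if (formula == "variance_components") {
    (ms$ms_subjects - ms$ms_error) / (ms$ms_subjects + ms$ms_error)
  } else {
    ms$ms_subjects / (ms$ms_subjects + ms$ms_error)
  }
  list(icc_c = icc, ms_subjects = ms$ms_subjects, ms_error = ms$ms_error)
}

#' Difference-score SD implied by a single-session SD and an ICC
#'
#' When only the pre- (or post-) test SD is known, the SD of difference
#' scores can be replaced by `SD_pre * sqrt(1 - ICC)`.
#'
#' @param sd_single_session positive single-session SD.
#' @param icc reliability in `[0, 1)`.
#' @return non-negative number.
#' @examples
#' sd_diff_from_icc(1.2, 0.75)  # 0.6
#' @export
sd_diff_from_icc <- function(sd_single_session, icc) {
  if (!is.finite(icc) || icc >= 1) {
    stop("`icc` must be finite and < 1", call. = FALSE)
  }
  if (!is.finite(sd_single_session) || sd_single_session < 0) {
    stop("`sd_single_session` must be >= 0", call. = FALSE)
  }
  sd_single_session * sqrt(1 - icc)
}
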