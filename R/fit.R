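# The central model fit: per-parameter retest reliability with a classed
# result object and the usual methods.

#' Fit a test-retest reliability analysis
#'
#' The workhorse of the package. For every parameter in a long-format
#' paired-assessment table it:
#' \enumerate{
#'   \item pairs session-1 and session-2 values per participant (dropping
#'     and counting participants missing a session);
#'   \item flags difference-score outliers (`|d|` above
#'     `diff_outlier_threshold`) and excludes them from everything
#'     downstream;
#'   \item estimates `SD_diff`, the retest confidence interval
#'     `CI = ci_multiplier * SD_diff` and the significant-change threshold
#'     `SC = sqrt(2) * CI`;
#'   \item estimates the consistency ICC from the two-way
#'     subjects-by-sessions decomposition;
#'   \item tests the learning effect (paired t-test on `session2 -
#'     session1`) and controls the false discovery rate across the whole
#'     parameter family;
#'   \item if trial-level data are supplied, pools per-series SEMs into
#'     the intra-subject error `IS = SEM_pooled * sqrt(2) * ci_multiplier`
#'     and reports it relative to SC.
#' }
#'
#' @param data long-format data frame (or file path) with columns
#'   `participant`, `session` (1/2), `task`, `parameter`, `value`; see
#'   [read_assessments()].
#' @param trials optional trial-level data frame with columns
#'   `participant`, `session`, `task`, `parameter`, `trial`, `value`.
#' @param config a [threshold_config()].
#' @param fdr_family `"all"` (battery-wide correction, default) or
#'   `"task"`.
#' @return an object of class `"retest_reliability"`: a list with
#'   `results` (one row per parameter: `parameter`, `task`, `n_pairs`,
#'   `n_outliers_removed`, `sd_diff`, `ci`, `sc`, `icc_c`, `ms_subjects`,
#'   `ms_error`, `mean_diff`, `t_statistic`, `df`, `p_value`, `q_value`,
#'   `significant_raw`, `significant_fdr`, `pooled_sem`, `is_error`,
#'   `is_error_ratio`), `pairs` (the flagged [paired_observations()]),
#'   `n_excluded`, `config`, `fdr_family` and `call`.
#' @seealso [summary.retest_reliability()], [plot.retest_reliability()],
#'   [simulate.retest_reliability()], [write_reliability_report()]
#' @examples
#' sim <- simulate_assessments(sim_config(seed = 42))
#' fit <- retest_reliability(sim$assessments, trials = sim$trials)
#' fit
#' head(coef(fit))
#' @export
retest_reliability <- function(data, trials = NULL,
                               config = threshold_config(),
                               fdr_family = c("all", "task")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(config, "threshold_config"))
  df <- read_assessments(data)
  paired <- pair_observations(df)
  pairs <- lapply(paired$pairs, flag_difference_outliers,
                  threshold = config$diff_outlier_threshold)

  rel_rows <- lapply(pairs, function(pr) {
    cs <- compute_ci_sc(pr, config)
    icc <- icc_consistency(pr, config$icc_formula)
    data.frame(parameter = pr$parameter, task = pr$task,
               n_pairs = cs$n_pairs,
               n_outliers_removed = cs$n_outliers_removed,
               sd_diff = cs$sd_diff, ci = cs$ci, sc = cs$sc,
               icc_c = icc$icc_c, ms_subjects = icc$ms_subjects,
               ms_error = icc$ms_error)
  })
  res <- do.call(rbind, rel_rows)
  rownames(res) <- NULL

  le <- learning_effect_table(pairs, config, fdr_family)
  res <- merge(res, le[, setdiff(names(le), c("task", "n_pairs"))],
               by = "parameter", sort = FALSE)

  res$pooled_sem <- NA_real_
  res$is_error <- NA_real_
  res$is_error_ratio <- NA_real_
  if (!is.null(trials) && nrow(trials) > 0) {
    for (p in intersect(unique(trials$parameter), res$parameter)) {
      sub <- trials[trials$parameter == p, ]
      i <- match(p, res$parameter)
      ie <- is_error(sub, sc = res$sc[i],
                     ci_multiplier = config$ci_multiplier)
      res$pooled_sem[i] <- ie$pooled_sem
      res$is_error[i] <- ie$is_error
      res$is_error_ratio[i] <- ie$ratio_to_sc
    }
  }

  structure(
    list(results = res, pairs = pairs, n_excluded = paired$n_excluded,
         config = config, fdr_family = fdr_family, call = match.call()),
    class = "retest_reliability"
  )
}

#' @export
print.retest_reliability <- function(x, ...) {
  res <- x$results
  cat("Test-retest reliability analysis\n")
  cat(sprintf("  %d parameter(s) across %d task(s); %d-%d pairs each\n",
              nrow(res), length(unique(res$task)),
              min(res$n_pairs), max(res$n_pairs)))
  cat(sprintf("  difference outliers removed: %d; participants missing a session: %d\n",
              sum(res$n_outliers_removed), sum(x$n_excluded)))
  cat(sprintf("  CI range %.2f-%.2f (multiplier %.2f), SC range %.2f-%.2f\n",
              min(res$ci), max(res$ci), x$config$ci_multiplier,
              min(res$sc), max(res$sc)))
  cat(sprintf("  ICC-C range %.2f-%.2f (%s)\n", min(res$icc_c),
              max(res$icc_c), x$config$icc_formula))
  cat(sprintf("  learning effects: %d/%d raw p < %.2f, %d FDR-significant\n",
              sum(res$significant_raw), nrow(res), x$config$alpha,
              sum(res$significant_fdr)))
  invisible(x)
}

#' Summarize a fitted reliability analysis
#'
#' @param object a [retest_reliability()] fit.
#' @param ... unused.
#' @return a `"summary.retest_reliability"` list with the per-parameter
#'   table plus battery-level summaries: mean/range of CI, SC and ICC-C,
#'   counts of significant learning effects, the share of ICC-C values
#'   above 0.50 and 0.75, and total exclusions.
#' @export
summary.retest_reliability <- function(object, ...) {
  res <- object$results
  rng <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  out <- list(
    results = res,
    n_parameters = nrow(res),
    ci = rng(res$ci), sc = rng(res$sc), icc = rng(res$icc_c),
    learning = rng(res$mean_diff),
    n_significant_raw = sum(res$significant_raw),
    n_significant_fdr = sum(res$significant_fdr),
    prop_icc_above_0.5 = mean(res$icc_c > 0.5),
    prop_icc_above_0.75 = mean(res$icc_c > 0.75),
    n_outliers_removed = sum(res$n_outliers_removed),
    n_excluded_missing_session = sum(object$n_excluded),
    config = object$config
  )
  class(out) <- "summary.retest_reliability"
  out
}

#' @export
print.summary.retest_reliability <- function(x, ...) {
  fmt <- function(v) sprintf("mean %.2f (range %.2f to %.2f)",
                             v["mean"], v["min"], v["max"])
  cat("Test-retest reliability summary\n")
  cat(sprintf("  parameters analysed:      %d\n", x$n_parameters))
  cat(sprintf("  confidence interval:      %s\n", fmt(x$ci)))
  cat(sprintf("  significant change:       %s\n", fmt(x$sc)))
  cat(sprintf("  learning effect:          %s\n", fmt(x$learning)))
  cat(sprintf("  ICC-C:                    %s\n", fmt(x$icc)))
  cat(sprintf("  ICC-C > 0.50 / > 0.75:    %.0f%% / %.0f%%\n",
              100 * x$prop_icc_above_0.5, 100 * x$prop_icc_above_0.75))
  cat(sprintf("  learning p < %.2f:         %d (FDR-significant: %d)\n",
              x$config$alpha, x$n_significant_raw, x$n_significant_fdr))
  cat(sprintf("  exclusions: %d difference outlier(s), %d missing-session participant(s)\n",
              x$n_outliers_removed, x$n_excluded_missing_session))
  invisible(x)
}

#' Per-parameter estimates of a reliability fit
#'
#' @param object a [retest_reliability()] fit.
#' @param ... unused.
#' @return numeric matrix (parameters x estimates) with columns `sd_diff`,
#'   `ci`, `sc`, `icc_c`, `mean_diff`.
#' @export
coef.retest_reliability <- function(object, ...) {
  res <- object$results
  m <- as.matrix(res[, c("sd_diff", "ci", "sc", "icc_c", "mean_diff")])
  rownames(m) <- res$parameter
  m
}

#' Centered difference scores of a reliability fit
#'
#' Residuals on the difference-score scale: for each unflagged pair,
#' `(session2 - session1) - mean_diff` of its parameter. Under the model
#' these are mean-zero with SD `SD_diff`.
#'
#' @param object a [retest_reliability()] fit.
#' @param ... unused.
#' @return named list of numeric vectors, one per parameter.
#' @export
residuals.retest_reliability <- function(object, ...) {
  res <- object$results
  lapply(stats::setNames(res$parameter, res$parameter), function(p) {
    pr <- object$pairs[[p]]
    u <- unflagged_(pr)
    (u$s2 - u$s1) - res$mean_diff[match(p, res$parameter)]
  })
}

#' Cumulative-distribution panels of a reliability fit
#'
#' Base-graphics panels of the per-parameter confidence intervals,
#' learning effects and ICC-C values, each sorted ascending against its
#' cumulative fraction — the battery-level presentation of where the bulk
#' of each distribution lies. Reference lines: the no-skill CI
#' (`ci_multiplier`, where retest error matches full between-subject
#' spread), zero learning effect, and the 0.50 / 0.75 ICC conventions.
#'
#' @param x a [retest_reliability()] fit.
#' @param which subset of `c("ci", "learning", "icc")`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.retest_reliability <- function(x, which = c("ci", "learning", "icc"),
                                    ...) {
  which <- match.arg(which, several.ok = TRUE)
  res <- x$results
  panels <- list(
    ci = list(v = res$ci, lab = "Confidence interval",
              ref = x$config$ci_multiplier),
    learning = list(v = res$mean_diff, lab = "Learning effect", ref = 0),
    icc = list(v = res$icc_c, lab = "ICC-C", ref = c(0.5, 0.75))
  )[which]
  old <- graphics::par(mfrow = c(1, length(panels)))
  on.exit(graphics::par(old))
  for (p in panels) {
    v <- sort(p$v)
    graphics::plot(v, seq_along(v) / length(v), type = "s",
                   xlab = p$lab, ylab = "Cumulative fraction", ...)
    graphics::abline(v = p$ref, lty = 2)
  }
  invisible(x)
}

#' Simulate new datasets from a fitted reliability analysis
#'
#' Parametric resampling: converts each parameter's estimates back into
#' generative variance components (`sigma_error = sd_diff / sqrt(2)`,
#' `sigma_subject` from the ICC as
#' `sigma_error * sqrt(icc / (1 - icc))`, learning shift = `mean_diff`)
#' and draws new paired datasets of the same size with
#' [simulate_assessments()]. ICC estimates are clamped to `[0, 0.99]`
#' before back-conversion so the implied components stay finite.
#'
#' @param object a [retest_reliability()] fit.
#' @param nsim number of datasets (default 1).
#' @param seed integer seed for the first dataset; dataset i uses
#'   `seed + i - 1`.
#' @param ... unused.
#' @return list of `nsim` long-format assessment data frames.
#' @export
simulate.retest_reliability <- function(object, nsim = 1, seed = 1L, ...) {
  res <- object$results
  lapply(seq_len(nsim), function(i) {
    sets <- lapply(seq_len(nrow(res)), function(k) {
      sigma_e <- res$sd_diff[k] / sqrt(2)
      icc <- min(max(res$icc_c[k], 0), 0.99)
      sigma_s <- sigma_e * sqrt(icc / (1 - icc))
      cfg <- sim_config(
        n_participants = res$n_pairs[k],
        parameters = list(parameter_spec(res$parameter[k], res$task[k])),
        sigma_subject = sigma_s, sigma_error = sigma_e,
        learning_shift = res$mean_diff[k], sigma_trial = 0,
        outlier_rate = 0,
        seed = (as.integer(seed) + i - 1L + k * 131L) %% .Machine$integer.max
      )
      simulate_assessments(cfg)$assessments
    })
    do.call(rbind, sets)
  })
}
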