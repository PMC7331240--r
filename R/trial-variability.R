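# Intra-subject (within-session) error from trial-level data: how much of
# the significant-change threshold is attributable to averaging over a
# finite number of trials.

#' Standard error of the mean of one trial series
#'
#' Sample SD of the trials (n - 1 denominator) divided by the square root
#' of the number of trials: the uncertainty of the session score as an
#' estimate of the participant's true session mean.
#'
#' @param values numeric vector of at least 2 trial measurements.
#' @return non-negative number.
#' @examples
#' series_sem(c(1, 2, 3))  # 1 / sqrt(3)
#' @export
series_sem <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 trials to compute an SEM", call. = FALSE)
  }
  stats::sd(values) / sqrt(length(values))
}

#' Intra-subject error pooled across participants and sessions
#'
#' Computes the per-series SEM for every participant and session, pools
#' them across the dataset, and scales the pooled SEM by `sqrt(2) * 1.64`
#' so it is directly comparable to the significant-change threshold
#' (`SC = SD_diff * sqrt(2) * 1.64`). Pooling is root-mean-square by
#' default (SEMs are standard deviations of estimators, so they combine in
#' quadrature); arithmetic-mean pooling is available for sensitivity
#' analysis.
#'
#' @param series list of numeric trial vectors (one per participant and
#'   session), or a data frame with columns `participant`, `session`,
#'   `value` (split internally).
#' @param sc significant-change threshold to compare against (> 0).
#' @param pooling `"rms"` (default) or `"mean"`.
#' @param ci_multiplier CI width in SDs (default 1.64).
#' @return list with `pooled_sem`, `is_error`
#'   (`pooled_sem * sqrt(2) * ci_multiplier`), `ratio_to_sc` and
#'   `n_series`.
#' @export
is_error <- function(series, sc, pooling = c("rms", "mean"),
                     ci_multiplier = 1.64) {
  pooling <- match.arg(pooling)
  if (!is.finite(sc) || sc <= 0) stop("`sc` must be > 0", call. = FALSE)
  if (is.data.frame(series)) {
    series <- split(series$value,
                    interaction(series$participant, series$session,
                                drop = TRUE))
  }
  series <- Filter(function(v) sum(is.finite(v)) >= 2L, series)
  if (length(series) == 0L) {
    stop("no series with at least 2 trials", call. = FALSE)
  }
  sems <- vapply(series, series_sem, numeric(1))
  pooled <- if (pooling == "rms") sqrt(mean(sems^2)) else mean(sems)
  err <- pooled * sqrt(2) * ci_multiplier
  list(pooled_sem = pooled, is_error = err, ratio_to_sc = err / sc,
       n_series = length(sems))
}
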