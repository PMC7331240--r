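# Probabilistic interpretation of scores: likelihood of true impairment
# given an observation, and three-way classification of change between two
# assessments.

#' Probabilistic impairment call for an observed score
#'
#' Divides the score axis into three regions around the impairment
#' threshold using the retest confidence interval: scores below
#' `threshold - ci` are statistically not impaired (< 5% chance the true
#' score exceeds the threshold), scores of at least `threshold + ci` are
#' statistically impaired (> 95% chance), and scores between are possibly
#' impaired. Region edges go to the more severe category. The probability
#' of true impairment treats the latent score as Normal around the
#' observation with SD `ci / ci_multiplier`, so an observation exactly at
#' the threshold is impaired with probability 0.5 and observations at
#' `threshold -/+ ci` with probability `1 - pnorm(1.64)` / `pnorm(1.64)`
#' (~5% / ~95%) under the default multiplier.
#'
#' @param observed numeric vector of observed scores (Z scale).
#' @param threshold impairment threshold (default 1.64, the 95th
#'   percentile of healthy performance).
#' @param ci retest confidence interval of the parameter (> 0).
#' @param ci_multiplier the multiplier that built `ci` from SD_diff
#'   (default 1.64).
#' @return data frame with columns `observed`, `category` (factor:
#'   `not_impaired`, `possibly_impaired`, `impaired`) and
#'   `probability_impaired`.
#' @examples
#' classify_impairment(c(0.5, 1.64, 3), threshold = 1.64, ci = 0.95)
#' @export
classify_impairment <- function(observed, threshold = 1.64, ci,
                                ci_multiplier = 1.64) {
  if (!is.finite(ci) || ci <= 0) stop("`ci` must be > 0", call. = FALSE)
  category <- ifelse(observed >= threshold + ci, "impaired",
                     ifelse(observed < threshold - ci, "not_impaired",
                            "possibly_impaired"))
  sigma <- ci / ci_multiplier
  # lower-tail form keeps precision far below the threshold
  prob <- stats::pnorm((observed - threshold) / sigma)
  data.frame(
    observed = observed,
    category = factor(category,
                      levels = c("not_impaired", "possibly_impaired",
                                 "impaired")),
    probability_impaired = prob
  )
}

#' Classify change between two assessments
#'
#' A follow-up score more than the significant-change threshold below the
#' first score is statistically improved; more than SC above is
#' statistically worse; anything between (edges included) is only possibly
#' changed. Assumes scores on a scale where lower is better (Z or Task
#' Score convention).
#'
#' @param score1,score2 numeric vectors: first and follow-up assessment
#'   scores.
#' @param sc significant-change threshold (> 0).
#' @return data frame with columns `score1`, `score2`, `change`
#'   (`score2 - score1`) and `category` (factor: `improved`,
#'   `possibly_changed`, `worse`).
#' @examples
#' classify_change(0, -1.5, sc = 1.34)  # improved
#' @export
classify_change <- function(score1, score2, sc) {
  if (!is.finite(sc) || sc <= 0) stop("`sc` must be > 0", call. = FALSE)
  d <- score2 - score1
  category <- ifelse(d < -sc, "improved",
                     ifelse(d > sc, "worse", "possibly_changed"))
  data.frame(
    score1 = score1, score2 = score2, change = d,
    category = factor(category,
                      levels = c("improved", "possibly_changed", "worse"))
  )
}
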