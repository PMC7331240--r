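# Score transforms: Zeta-scores, RSS / Mahalanobis distances, Task Scores,
# and the iterative de-skewing normalization used to build Z-Task Scores.

# complementary error function and its inverse, in terms of the Normal CDF
erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))
erfcinv_ <- function(y) -stats::qnorm(y / 2) / sqrt(2)

#' Zeta transform of a one-sided Z-score
#'
#' Folds a Z-score whose impairment direction is one-sided onto a
#' non-negative scale on which larger is always worse:
#' `sqrt(2) * erfcinv(0.5 * erfc(z / sqrt(2)))`, i.e. the standard-Normal
#' quantile of `(1 + pnorm(z)) / 2`. A Z of 0 (median performance) maps to
#' 0.6745, the 75th percentile of the standard Normal; very poor scores map
#' to large values and very good scores approach 0.
#'
#' Parameters on a "higher is better" scale must be sign-flipped to the
#' "higher is worse" convention before applying this transform.
#'
#' @param z numeric vector of finite Z-scores.
#' @return numeric vector of Zeta-scores, strictly increasing in `z`,
#'   taking values in (0, Inf).
#' @examples
#' zeta_transform(0)      # 0.6745
#' zeta_transform(1.64)   # ~1.955
#' @export
zeta_transform <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("`z` must be a numeric vector of finite values", call. = FALSE)
  }
  sqrt(2) * erfcinv_(0.5 * erfc_(z / sqrt(2)))
}

#' One-sided Task Score from a Z-Task Score
#'
#' Applies the same folding transform as [zeta_transform()] to a Z-Task
#' Score, yielding the one-sided Task Score: 0 is the best possible
#' performance and larger values are worse. A Task Score of 1 bounds about
#' 68.3% of a standard-Normal population of Z-Task Scores, mirroring the
#' +/-1 band of the two-sided scale.
#'
#' @param z_task_score numeric vector of finite Z-Task Scores.
#' @return numeric vector of non-negative Task Scores.
#' @seealso [task_score_ci()] for confidence bounds on this scale.
#' @export
task_score <- function(z_task_score) {
  if (!is.numeric(z_task_score) || any(!is.finite(z_task_score))) {
    stop("`z_task_score` must be a numeric vector of finite values",
         call. = FALSE)
  }
  zeta_transform(z_task_score)
}

#' Root-sum-square distance across parameter scores
#'
#' Euclidean length of the combined vector of two-sided parameter Z-scores
#' and one-sided Zeta-scores for one task: the raw composite that is
#' re-normalized into a Z-Task Score. Missing components are dropped from
#' the sum.
#'
#' @param z_two_sided numeric vector of two-sided Z-scores (may be empty).
#' @param zeta_one_sided numeric vector of Zeta-scores (may be empty).
#' @return single non-negative number.
#' @examples
#' rss_distance(c(3, 4), numeric(0))  # 5
#' @export
rss_distance <- function(z_two_sided = numeric(0), zeta_one_sided = numeric(0)) {
  comp <- c(as.numeric(z_two_sided), as.numeric(zeta_one_sided))
  comp <- comp[is.finite(comp)]
  if (length(comp) == 0L) {
    stop("no finite components to combine", call. = FALSE)
  }
  sqrt(sum(comp^2))
}

#' Mahalanobis distance of a parameter Z-score vector
#'
#' Covariance-aware alternative to [rss_distance()] used for M-Scores:
#' `sqrt(t(z) %*% solve(Sigma) %*% z)`. The covariance is ridge-regularized
#' by `ridge * trace(Sigma) / ncol(Sigma)` on the diagonal so near-singular
#' reference covariances remain invertible. With the identity covariance the
#' result equals the RSS distance.
#'
#' @param z numeric vector of parameter Z-scores.
#' @param covariance square covariance matrix, `length(z)` on each side.
#' @param ridge relative ridge term (default 1e-8).
#' @return single non-negative number.
#' @export
mahalanobis_distance <- function(z, covariance, ridge = 1e-8) {
  z <- as.numeric(z)
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance) ||
      nrow(covariance) != length(z)) {
    stop("`covariance` must be square with dimension length(z)",
         call. = FALSE)
  }
  sigma <- covariance +
    diag(ridge * sum(diag(covariance)) / ncol(covariance),
         ncol(covariance))
  sqrt(stats::mahalanobis(z, center = rep(0, length(z)), cov = sigma))
}

# Box-Cox transform; lambda ~ 0 falls back to the log limit
box_cox_ <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Fit the iterative de-skewing normalization
#'
#' Converts raw (or composite-distance) values to Z-scores the way reference
#' cohorts are normalized before Task-Score calculation: iteratively
#' (a) shift values to positivity, (b) de-skew with a maximum-likelihood
#' Box-Cox transform, (c) standardize to mean 0 / SD 1, and (d) trim
#' observations with |Z| greater than `z_outlier_threshold` (default 3.29,
#' the two-sided 0.001 tail). The loop repeats until a pass trims nothing or
#' `max_iterations` is reached. The returned model (shift, lambda, location,
#' scale) reproduces the final standardization exactly on its retained
#' training data and can be applied to new values with `predict()`.
#'
#' @param values numeric vector, at least 10 finite observations.
#' @param max_iterations maximum trimming passes (default 10).
#' @param z_outlier_threshold trimming threshold on |Z| (default 3.29).
#' @param lambda_grid search interval for the Box-Cox exponent
#'   (default `c(-5, 5)`).
#' @return an object of class `"normalization_model"` with fields
#'   `box_cox_lambda`, `shift`, `location`, `scale`, `n_outliers_trimmed`,
#'   `n_iterations`, and `retained` (standardized retained observations).
#' @seealso [predict.normalization_model()], [write_normalization_model()]
#' @export
fit_normalization <- function(values, max_iterations = 10,
                              z_outlier_threshold = 3.29,
                              lambda_grid = c(-5, 5)) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    stop("need at least 10 finite values to fit a normalization",
         call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("all values identical: scale is degenerate", call. = FALSE)
  }
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)

  retained <- values
  n_trimmed <- 0L
  iter <- 0L
  shift <- 0
  lambda <- NA_real_
  location <- NA_real_
  scale <- NA_real_
  z <- NULL

  repeat {
    iter <- iter + 1L
    shift <- if (min(retained) <= 0) 1 - min(retained) else 0
    y <- retained + shift
    # profile-likelihood Box-Cox fit; spline interpolation refines the grid
    bc <- MASS::boxcox(y ~ 1, lambda = seq(lambda_grid[1], lambda_grid[2],
                                           length.out = 201),
                       plotit = FALSE, interp = TRUE)
    lambda <- bc$x[which.max(bc$y)]
    t_vals <- box_cox_(y, lambda)
    location <- mean(t_vals)
    scale <- stats::sd(t_vals)
    if (scale == 0) stop("degenerate scale after transformation", call. = FALSE)
    z <- (t_vals - location) / scale
    keep <- abs(z) <= z_outlier_threshold
    if (all(keep) || iter >= max_iterations || sum(keep) < 10L) {
      z <- z[keep]
      n_trimmed <- n_trimmed + sum(!keep)
      break
    }
    n_trimmed <- n_trimmed + sum(!keep)
    retained <- retained[keep]
  }

  structure(
    list(box_cox_lambda = lambda, shift = shift, location = location,
         scale = scale, n_outliers_trimmed = n_trimmed, n_iterations = iter,
         retained = z),
    class = "normalization_model"
  )
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("Normalization model (iterative Box-Cox de-skew + |Z| trimming)\n")
  cat(sprintf("  lambda = %.4f, shift = %.4f\n", x$box_cox_lambda, x$shift))
  cat(sprintf("  location = %.4f, scale = %.4f\n", x$location, x$scale))
  cat(sprintf("  %d outlier(s) trimmed over %d iteration(s); %d retained\n",
              x$n_outliers_trimmed, x$n_iterations, length(x$retained)))
  invisible(x)
}

#' Apply a fitted normalization to new values
#'
#' @param object a `"normalization_model"`.
#' @param newdata numeric vector of raw values on the training scale.
#' @param ... unused.
#' @return numeric vector of Z-scores; values that are non-positive after
#'   the positivity shift cannot be Box-Cox transformed and return `NA`.
#' @export
predict.normalization_model <- function(object, newdata, ...) {
  y <- as.numeric(newdata) + object$shift
  out <- rep(NA_real_, length(y))
  ok <- is.finite(y) & y > 0
  if (any(!ok & is.finite(y))) {
    warning("values non-positive after shift returned as NA", call. = FALSE)
  }
  out[ok] <- (box_cox_(y[ok], object$box_cox_lambda) - object$location) /
    object$scale
  out
}

#' Z-Task Score of a composite distance against a reference cohort
#'
#' Fits [fit_normalization()] to a reference cohort's RSS (or Mahalanobis)
#' distances and standardizes `value` against it, yielding the two-sided
#' Z-Task Score.
#'
#' @param reference_rss numeric vector of at least 10 reference-cohort
#'   composite distances.
#' @param value numeric vector of distances to score.
#' @param ... passed to [fit_normalization()].
#' @return numeric vector of Z-Task Scores.
#' @export
z_task_score <- function(reference_rss, value, ...) {
  model <- fit_normalization(reference_rss, ...)
  predict(model, value)
}

#' Asymmetric confidence bounds on the one-sided Task Score
#'
#' Propagates a symmetric two-sided confidence interval `z +/- ci` through
#' the nonlinear one-sided transform: the bounds are
#' `task_score(z - ci)` and `task_score(z + ci)`. Because the transform
#' compresses the left tail toward 0, the interval is asymmetric around the
#' point estimate — the upper distance exceeds the lower distance, with
#' both approaching `ci` for large `z`.
#'
#' @param z_task_score numeric vector of finite Z-Task Scores.
#' @param ci half-width of the symmetric interval on the Z scale (> 0).
#' @return a data frame of class `"task_score_ci"` with columns
#'   `z_task_score`, `task_score`, `lower_bound`, `upper_bound`.
#' @examples
#' task_score_ci(0, ci = 1)
#' @export
task_score_ci <- function(z_task_score, ci) {
  if (!is.numeric(ci) || length(ci) != 1L || !is.finite(ci) || ci <= 0) {
    stop("`ci` must be a single positive number", call. = FALSE)
  }
  out <- data.frame(
    z_task_score = z_task_score,
    task_score = task_score(z_task_score),
    lower_bound = task_score(z_task_score - ci),
    upper_bound = task_score(z_task_score + ci)
  )
  class(out) <- c("task_score_ci", "data.frame")
  out
}

#' Serialize a normalization model to key-value text
#'
#' Writes the four transform constants (plus trimming metadata) as
#' `key = value` lines so reference-cohort normalizations are reproducible
#' across runs without refitting.
#'
#' @param model a `"normalization_model"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "normalization_model"))
  keys <- c("box_cox_lambda", "shift", "location", "scale",
            "n_outliers_trimmed", "n_iterations")
  lines <- vapply(keys, function(k) {
    sprintf("%s = %s", k, format(model[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalization model written by [write_normalization_model()]
#'
#' @param path file path.
#' @return a `"normalization_model"` (without retained training data).
#' @export
read_normalization_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    as.numeric(vapply(kv, `[`, character(1), 2L)),
    vapply(kv, `[`, character(1), 1L)
  )
  structure(
    list(box_cox_lambda = vals[["box_cox_lambda"]], shift = vals[["shift"]],
         location = vals[["location"]], scale = vals[["scale"]],
         n_outliers_trimmed = as.integer(vals[["n_outliers_trimmed"]]),
         n_iterations = as.integer(vals[["n_iterations"]]),
         retained = NULL),
    class = "normalization_model"
  )
}
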