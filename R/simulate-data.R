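# Synthetic paired-assessment generator: the ground-truth data model every
# downstream stage is tested against.

#' Describe one assessment parameter
#'
#' @param name parameter identifier (unique within a dataset).
#' @param task task identifier the parameter belongs to.
#' @param sidedness `"two_sided"` (impairment in either direction, e.g.
#'   laterality) or `"one_sided"` (impairment in one direction only).
#' @param direction for one-sided parameters, whether a higher raw Z is
#'   worse (`"higher_worse"`, e.g. reaction time) or better
#'   (`"higher_better"`, e.g. objects hit). Ignored for two-sided
#'   parameters.
#' @param n_trials trials performed per session; 0 means no trial-level
#'   data, otherwise at least 2.
#' @return a `"parameter_spec"` list.
#' @export
parameter_spec <- function(name, task,
                           sidedness = c("two_sided", "one_sided"),
                           direction = c("higher_worse", "higher_better"),
                           n_trials = 0) {
  sidedness <- match.arg(sidedness)
  direction <- match.arg(direction)
  if (sidedness == "two_sided") direction <- NA_character_
  n_trials <- as.integer(n_trials)
  if (n_trials != 0L && n_trials < 2L) {
    stop("`n_trials` must be 0 or at least 2", call. = FALSE)
  }
  structure(list(name = as.character(name), task = as.character(task),
                 sidedness = sidedness, direction = direction,
                 n_trials = n_trials),
            class = "parameter_spec")
}

#' Default parameter battery emulating a Kinarm Standard Tests run
#'
#' A compact stand-in for the KST battery: the three trial-based reaching
#' tasks (VGR with 20 trials, RVGR with 24, PM with 25, dominant and
#' non-dominant arms) plus the single-run tasks (OH, OHA, TMT, SPS, BOB),
#' with a mix of one- and two-sided parameters per task.
#'
#' @return list of [parameter_spec()] objects.
#' @export
kst_parameter_specs <- function() {
  reaching <- function(task, n_trials) {
    list(
      parameter_spec(paste0(task, ".reaction_time"), task, "one_sided",
                     "higher_worse", n_trials),
      parameter_spec(paste0(task, ".initial_direction_angle"), task,
                     "one_sided", "higher_worse", n_trials),
      parameter_spec(paste0(task, ".max_speed"), task, "one_sided",
                     "higher_better", n_trials),
      parameter_spec(paste0(task, ".path_length_ratio"), task, "two_sided",
                     n_trials = n_trials)
    )
  }
  c(
    reaching("VGR-D", 20), reaching("VGR-ND", 20),
    reaching("RVGR-D", 24), reaching("RVGR-ND", 24),
    reaching("PM-D", 25), reaching("PM-ND", 25),
    list(
      parameter_spec("OH.total_hits", "OH", "one_sided", "higher_better"),
      parameter_spec("OH.hand_bias", "OH", "two_sided"),
      parameter_spec("OHA.total_hits", "OHA", "one_sided", "higher_better"),
      parameter_spec("OHA.hand_bias", "OHA", "two_sided"),
      parameter_spec("TMT.test_time", "TMT", "one_sided", "higher_worse"),
      parameter_spec("SPS.shift_error", "SPS", "one_sided", "higher_worse"),
      parameter_spec("SPS.shift_bias", "SPS", "two_sided"),
      parameter_spec("BOB.mean_bar_angle", "BOB", "two_sided"),
      parameter_spec("BOB.balls_dropped", "BOB", "one_sided", "higher_worse")
    )
  )
}

#' Configuration for the paired-assessment generator
#'
#' Defines the generative model on the Z-score scale: for participant i,
#' parameter p, session j in \{1, 2\},
#' `x_ijp = s_ip + learning_shift * 1[j = 2] + e_ijp`, with subject effects
#' `s_ip ~ N(0, sigma_subject^2)` and session errors
#' `e_ijp ~ N(0, sigma_error^2)`; with probability `outlier_rate` an
#' observation is displaced by `+/- outlier_magnitude` (random sign). For
#' parameters with `n_trials > 0`, trial values are
#' `y_ijpt = x_ijp + tau, tau ~ N(0, sigma_trial^2)`.
#'
#' Defaults reflect a healthy retest cohort of a robotic assessment battery:
#' 56 participants, between-subject SD 0.7 and between-session error SD 0.5
#' in Z-units (a consistency ICC of 0.66 and a retest CI of ~1.16), a small
#' practice benefit of -0.2 Z at the second session, trial-to-trial SD 0.3,
#' and rare large outliers (rate 0.005, magnitude 5 Z).
#'
#' @param n_participants number of participants (>= 2).
#' @param parameters list of [parameter_spec()]s.
#' @param sigma_subject between-subject SD, Z-units (>= 0).
#' @param sigma_error within-subject between-session error SD, Z-units.
#' @param learning_shift additive session-2 offset, Z-units (signed;
#'   negative = better performance at retest).
#' @param sigma_trial within-session trial SD, Z-units.
#' @param outlier_rate per-observation probability of an injected outlier.
#' @param outlier_magnitude displacement of injected outliers, Z-units.
#' @param seed integer RNG seed; identical seed + config reproduce the
#'   dataset bit-for-bit.
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(n_participants = 56,
                       parameters = kst_parameter_specs(),
                       sigma_subject = 0.7,
                       sigma_error = 0.5,
                       learning_shift = -0.2,
                       sigma_trial = 0.3,
                       outlier_rate = 0.005,
                       outlier_magnitude = 5,
                       seed = 1L) {
  sds <- c(sigma_subject, sigma_error, sigma_trial, outlier_magnitude)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all SDs and the outlier magnitude must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.finite(learning_shift)) {
    stop("`learning_shift` must be finite", call. = FALSE)
  }
  if (!is.finite(outlier_rate) || outlier_rate < 0 || outlier_rate > 1) {
    stop("`outlier_rate` must be in [0, 1]", call. = FALSE)
  }
  if (n_participants < 2) stop("need at least 2 participants", call. = FALSE)
  if (!all(vapply(parameters, inherits, logical(1), "parameter_spec"))) {
    stop("`parameters` must be a list of parameter_spec objects",
         call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 parameters = parameters,
                 sigma_subject = sigma_subject, sigma_error = sigma_error,
                 learning_shift = learning_shift, sigma_trial = sigma_trial,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a paired-assessment dataset with known ground truth
#'
#' Draws session-1/session-2 Z-scores per participant and parameter from
#' the generative model in [sim_config()], plus trial-level series for
#' parameters with `n_trials > 0`. The true variance components are
#' returned alongside the data so estimators can be checked against them.
#'
#' @param config a [sim_config()].
#' @return an `"assessment_sim"` list with elements
#'   \describe{
#'     \item{assessments}{long data frame: `participant`, `session` (1/2),
#'       `task`, `parameter`, `value`.}
#'     \item{trials}{long data frame (`participant`, `session`, `task`,
#'       `parameter`, `trial`, `value`) or `NULL` if no parameter carries
#'       trials.}
#'     \item{truth}{list of the generating `sigma_subject`, `sigma_error`,
#'       `learning_shift`, `sigma_trial`, `outlier_rate`,
#'       `n_outliers_injected`, and the implied `expected_icc` and
#'       `expected_sd_diff`.}
#'   }
#' @export
simulate_assessments <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))

  assess <- vector("list", length(config$parameters))
  trials <- vector("list", length(config$parameters))
  n_outliers <- 0L

  for (k in seq_along(config$parameters)) {
    p <- config$parameters[[k]]
    s <- stats::rnorm(n, 0, config$sigma_subject)
    x <- cbind(
      s + stats::rnorm(n, 0, config$sigma_error),
      s + config$learning_shift + stats::rnorm(n, 0, config$sigma_error)
    )
    out_mask <- matrix(stats::runif(2 * n) < config$outlier_rate, n, 2)
    if (any(out_mask)) {
      signs <- sample(c(-1, 1), sum(out_mask), replace = TRUE)
      x[out_mask] <- x[out_mask] + signs * config$outlier_magnitude
      n_outliers <- n_outliers + sum(out_mask)
    }
    assess[[k]] <- data.frame(
      participant = rep(ids, 2L),
      session = rep(c(1L, 2L), each = n),
      task = p$task, parameter = p$name,
      value = c(x[, 1], x[, 2])
    )
    if (p$n_trials > 0L) {
      nt <- p$n_trials
      trials[[k]] <- data.frame(
        participant = rep(rep(ids, 2L), each = nt),
        session = rep(rep(c(1L, 2L), each = n), each = nt),
        task = p$task, parameter = p$name,
        trial = rep(seq_len(nt), 2L * n),
        value = rep(c(x[, 1], x[, 2]), each = nt) +
          stats::rnorm(2L * n * nt, 0, config$sigma_trial)
      )
    }
  }

  trials <- trials[!vapply(trials, is.null, logical(1))]
  structure(
    list(
      assessments = do.call(rbind, assess),
      trials = if (length(trials)) do.call(rbind, trials) else NULL,
      truth = list(
        sigma_subject = config$sigma_subject,
        sigma_error = config$sigma_error,
        learning_shift = config$learning_shift,
        sigma_trial = config$sigma_trial,
        outlier_rate = config$outlier_rate,
        n_outliers_injected = n_outliers,
        expected_icc = config$sigma_subject^2 /
          (config$sigma_subject^2 + config$sigma_error^2),
        expected_sd_diff = sqrt(2) * config$sigma_error
      ),
      config = config
    ),
    class = "assessment_sim"
  )
}

#' @export
print.assessment_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic paired assessments: %d participants x %d parameters\n",
    x$config$n_participants, length(x$config$parameters)))
  cat(sprintf("  sigma_subject = %.3f, sigma_error = %.3f, shift = %.3f\n",
              x$truth$sigma_subject, x$truth$sigma_error,
              x$truth$learning_shift))
  cat(sprintf("  expected ICC-C = %.3f, expected SD_diff = %.3f\n",
              x$truth$expected_icc, x$truth$expected_sd_diff))
  if (!is.null(x$trials)) {
    cat(sprintf("  trial-level rows: %d\n", nrow(x$trials)))
  }
  invisible(x)
}

#' Write a simulated dataset (and its ground truth) to disk
#'
#' Writes the long-format assessment table (and trial table, if present) as
#' comma-separated text, and the generating parameters as a `key = value`
#' sidecar so a run is fully reconstructible.
#'
#' @param sim an `"assessment_sim"`.
#' @param dir output directory, created if absent.
#' @return character vector of the files written, invisibly.
#' @export
write_assessment_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "assessment_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # 17 significant digits make the text round-trip bit-exact for doubles
  full_precision <- function(df) {
    df$value <- sprintf("%.17g", df$value)
    df
  }
  files <- file.path(dir, "assessments.csv")
  utils::write.csv(full_precision(sim$assessments), files, row.names = FALSE)
  if (!is.null(sim$trials)) {
    f <- file.path(dir, "trials.csv")
    utils::write.csv(full_precision(sim$trials), f, row.names = FALSE)
    files <- c(files, f)
  }
  truth_path <- file.path(dir, "truth.txt")
  keys <- c("sigma_subject", "sigma_error", "learning_shift", "sigma_trial",
            "outlier_rate", "n_outliers_injected", "expected_icc",
            "expected_sd_diff")
  writeLines(
    c(sprintf("seed = %d", sim$config$seed),
      sprintf("n_participants = %d", sim$config$n_participants),
      vapply(keys, function(k) sprintf("%s = %s", k,
                                       format(sim$truth[[k]], digits = 15)),
             character(1))),
    truth_path)
  invisible(c(files, truth_path))
}
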