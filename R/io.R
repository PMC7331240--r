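# Reading long-format assessment tables, pairing sessions, and writing the
# end-to-end report files.

#' Read a long-format assessment table
#'
#' Expects delimited text (or an equivalent data frame) with columns
#' `participant`, `session` (coded 1 and 2), `task`, `parameter`, `value`.
#' Validates the coding and rejects duplicate
#' (participant, session, parameter) rows.
#'
#' @param x path to a comma-separated file with a header row, or a data
#'   frame already in that shape.
#' @return validated data frame with the five columns above.
#' @export
read_assessments <- function(x) {
  df <- if (is.data.frame(x)) x else utils::read.csv(x, stringsAsFactors = FALSE)
  required <- c("participant", "session", "task", "parameter", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[required]
  if (!all(df$session %in% c(1, 2))) {
    stop("`session` must be coded 1 and 2", call. = FALSE)
  }
  df$session <- as.integer(df$session)
  df$value <- as.numeric(df$value)
  key <- paste(df$participant, df$session, df$parameter, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant, session, parameter) rows", call. = FALSE)
  }
  df
}

#' Pair first- and second-session observations per parameter
#'
#' Pivots a validated long table to one [paired_observations()] object per
#' parameter. Participants missing either session for a parameter are
#' dropped and counted.
#'
#' @param df a data frame as returned by [read_assessments()].
#' @return list with `pairs` (named list of [paired_observations()]) and
#'   `n_excluded` (named integer vector of participants dropped per
#'   parameter for lacking a session).
#' @export
pair_observations <- function(df) {
  params <- unique(df$parameter)
  pairs <- vector("list", length(params))
  names(pairs) <- params
  n_excluded <- stats::setNames(integer(length(params)), params)
  for (p in params) {
    sub <- df[df$parameter == p, ]
    s1 <- sub[sub$session == 1L, ]
    s2 <- sub[sub$session == 2L, ]
    ids <- union(s1$participant, s2$participant)
    common <- intersect(s1$participant, s2$participant)
    n_excluded[[p]] <- length(ids) - length(common)
    pairs[[p]] <- paired_observations(
      participant_ids = common,
      session1 = s1$value[match(common, s1$participant)],
      session2 = s2$value[match(common, s2$participant)],
      parameter = p,
      task = sub$task[1]
    )
  }
  list(pairs = pairs, n_excluded = n_excluded)
}

#' Published reliability summary of the Kinarm Standard Tests task scores
#'
#' The printed per-task test-retest summary for the 11 Z-Task Scores of a
#' healthy-cohort Kinarm Standard Tests study (the raw cohort data are not
#' publicly deposited): outliers removed, significant change, assessment
#' confidence interval, learning effect with its p-value, and consistency
#' ICC. Useful as a reference point for synthetic studies and for checking
#' report arithmetic (e.g. `significant_change = sqrt(2) * confidence`).
#'
#' The two `p < 1e-4` entries are stored as `1e-4`.
#'
#' @return data frame with columns `task`, `outliers_removed`,
#'   `significant_change`, `confidence_interval`, `learning_effect`,
#'   `le_p_value`, `icc_consistency`.
#' @export
kst_reference_summary <- function() {
  path <- system.file("extdata", "kst_task_score_summary.csv",
                      package = "retest", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

format_kv_ <- function(x) {
  vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s",
            k, if (is.numeric(v)) format(v, digits = 15) else as.character(v))
  }, character(1))
}

#' Write the full report of a fitted reliability analysis
#'
#' Writes, into `dir`:
#' \itemize{
#'   \item `results_full.csv` — the per-parameter table at full precision;
#'   \item `results_rounded.csv` — the same table rounded to 2 decimals,
#'     the presentation convention of published summaries;
#'   \item `cumulative_ci.csv`, `cumulative_learning.csv`,
#'     `cumulative_icc.csv` — ascending sorted values with cumulative
#'     fractions (the cumulative-distribution presentation);
#'   \item `manifest.txt` — thresholds, options and counts as key-value
#'     text.
#' }
#'
#' @param fit a [retest_reliability()] object.
#' @param dir output directory, created if absent.
#' @return character vector of files written, invisibly.
#' @export
write_reliability_report <- function(fit, dir) {
  stopifnot(inherits(fit, "retest_reliability"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- fit$results
  files <- character(0)

  f <- file.path(dir, "results_full.csv")
  utils::write.csv(res, f, row.names = FALSE)
  files <- c(files, f)

  rounded <- res
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round, digits = 2)
  f <- file.path(dir, "results_rounded.csv")
  utils::write.csv(rounded, f, row.names = FALSE)
  files <- c(files, f)

  cum_table <- function(v) {
    v <- sort(v[is.finite(v)])
    data.frame(rank = seq_along(v), value = v,
               cumulative_fraction = seq_along(v) / length(v))
  }
  cum_cols <- c(ci = "ci", learning = "mean_diff", icc = "icc_c")
  for (nm in names(cum_cols)) {
    f <- file.path(dir, sprintf("cumulative_%s.csv", nm))
    utils::write.csv(cum_table(res[[cum_cols[[nm]]]]), f, row.names = FALSE)
    files <- c(files, f)
  }

  cfg <- fit$config
  manifest <- c(
    format_kv_(list(
      package_version = as.character(utils::packageVersion("retest")),
      n_parameters = nrow(res),
      n_pairs_excluded_missing_session = sum(fit$n_excluded),
      n_difference_outliers_removed = sum(res$n_outliers_removed),
      fdr_family = fit$fdr_family
    )),
    format_kv_(unclass(cfg))
  )
  f <- file.path(dir, "manifest.txt")
  writeLines(manifest, f)
  files <- c(files, f)
  invisible(files)
}

#' Run the full analysis pipeline from files to report
#'
#' Reads a long-format assessment table (and optional trial-level table),
#' fits [retest_reliability()], and writes the report files with
#' [write_reliability_report()]. If any stage fails, partial outputs
#' written to `output_dir` by this call are removed before the error is
#' re-thrown with a stage label.
#'
#' @param input path (or data frame) of the assessment table.
#' @param trials optional path (or data frame) of the trial-level table
#'   with columns `participant`, `session`, `task`, `parameter`, `trial`,
#'   `value`.
#' @param output_dir directory for report files.
#' @param config a [threshold_config()].
#' @param fdr_family passed to [learning_effect_table()].
#' @return the fitted `"retest_reliability"` object, invisibly.
#' @export
run_retest_pipeline <- function(input, trials = NULL, output_dir,
                                config = threshold_config(),
                                fdr_family = c("all", "task")) {
  stage <- "read"
  before <- if (dir.exists(output_dir)) list.files(output_dir) else character(0)
  tryCatch({
    df <- read_assessments(input)
    trial_df <- if (is.null(trials)) NULL
                else if (is.data.frame(trials)) trials
                else utils::read.csv(trials, stringsAsFactors = FALSE)
    stage <- "fit"
    fit <- retest_reliability(df, trials = trial_df, config = config,
                              fdr_family = fdr_family)
    stage <- "report"
    write_reliability_report(fit, output_dir)
    invisible(fit)
  }, error = function(e) {
    if (dir.exists(output_dir)) {
      created <- setdiff(list.files(output_dir), before)
      unlink(file.path(output_dir, created))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
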