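#' Endpoint summary of a progressive-ratio session
#'
#' @param session Tibble of one PR session's trial rows.
#' @return One-row tibble: `breakpoint`, `total_target_touches`,
#'   `total_blank_touches`, `mean_collect_latency_s`, `beam_break_rate`
#'   (breaks per minute of session), `session_duration_s`, `prefed`.
#' @export
summarize_pr <- function(session) {
  if (nrow(session) > 0 && !all(session$task == "PR")) {
    abort("summarize_pr() is defined for PR sessions only.")
  }
  lat <- session$reward_collect_latency_s
  dur <- if (nrow(session) > 0) session$session_duration_s[1] else NA_real_
  beam <- if (nrow(session) > 0) session$beam_breaks[1] else NA_integer_
  tibble::tibble(
    breakpoint = breakpoint(session),
    total_target_touches = sum(session$n_target_touches),
    total_blank_touches = sum(session$n_blank_touches),
    mean_collect_latency_s = if (all(is.na(lat))) NA_real_
                             else mean(lat, na.rm = TRUE),
    beam_break_rate = beam / (dur / 60),
    session_duration_s = dur,
    prefed = if (nrow(session) > 0) session$prefed[1] else NA)
}

#' Summarise PR endpoints across a cohort
#'
#' @param cohort A [cohort_table()].
#' @return Tibble with one row per PR session per animal.
#' @export
summarize_pr_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  pr <- dplyr::filter(cohort$trials, .data$task == "PR")
  if (nrow(pr) == 0L) {
    return(tibble::tibble(animal_id = character(), genotype = character(),
                          schedule_step = integer(), session_index = integer(),
                          breakpoint = integer(), total_target_touches = integer(),
                          total_blank_touches = integer(),
                          mean_collect_latency_s = double(),
                          beam_break_rate = double(),
                          session_duration_s = double(), prefed = logical()))
  }
  groups <- dplyr::group_split(
    dplyr::group_by(pr, .data$animal_id, .data$schedule_step,
                    .data$session_index))
  purrr::map_dfr(groups, function(s) {
    dplyr::bind_cols(
      tibble::tibble(animal_id = s$animal_id[1], genotype = s$genotype[1],
                     schedule_step = s$schedule_step[1],
                     session_index = s$session_index[1]),
      summarize_pr(s))
  })
}

#' Segment a 30-trial extinction session into response phases
#'
#' Splits the session into early (trials 1–10), middle (11–20) and late
#' (21–30) phases and reports the response percentage of each phase
#' (percent of non-omitted trials, denominator 10 by default).
#'
#' @param session Tibble of one extinction session's trial rows; must
#'   contain exactly 30 trials.
#' @param denominator `"phase"` (percent of the 10 phase trials, default)
#'   or `"session"` (percent of all 30 trials).
#' @return One-row tibble: `session_index`, `early_pct`, `middle_pct`,
#'   `late_pct`.
#' @export
segment_extinction_phases <- function(session,
                                      denominator = c("phase", "session")) {
  denominator <- match.arg(denominator)
  n <- nrow(session)
  if (n != 30L) {
    abort(sprintf("extinction session must have exactly 30 trials, got %d", n))
  }
  session <- dplyr::arrange(session, .data$trial_index)
  resp <- !session$omitted
  denom <- if (denominator == "phase") 10 else 30
  tibble::tibble(
    session_index = session$session_index[1],
    early_pct = 100 * sum(resp[1:10]) / denom,
    middle_pct = 100 * sum(resp[11:20]) / denom,
    late_pct = 100 * sum(resp[21:30]) / denom)
}

#' Per-session response percentage of an extinction series
#'
#' @param sessions Tibble of extinction trial rows (one animal, ordered
#'   sessions of 30 trials).
#' @return Tibble: `session_index`, `response_pct`, `omission_pct`
#'   (summing to 100).
#' @export
omission_response_pct <- function(sessions) {
  out <- dplyr::summarise(
    dplyr::group_by(sessions, .data$session_index),
    response_pct = 100 * mean(!.data$omitted), .groups = "drop")
  out$omission_pct <- 100 - out$response_pct
  dplyr::arrange(out, .data$session_index)
}

#' Perseverative errors before the reversal criterion
#'
#' Perseveration after a contingency reversal is indexed by the errors an
#' animal makes while its accuracy is still below criterion. The
#' criterion session is found with [detect_criterion()] (accuracy at or
#' above threshold on `window` consecutive sessions); perseverative
#' errors are the incorrect responses summed over sessions strictly
#' *before the first session of the qualifying pair* — the epoch in which
#' responding is dominated by the old contingency. Trials and errors to
#' criterion are counted through the criterion session itself.
#'
#' @param sessions Tibble of reversal trial rows (one animal, ordered
#'   sessions, `correct` flags present).
#' @param crit A [criterion_spec()]; default accuracy >= 50% on 2
#'   consecutive sessions.
#' @return One-row tibble: `sessions_to_criterion`, `trials_to_criterion`,
#'   `errors_to_criterion`, `perseverative_errors`, `criterion_met`.
#' @export
count_perseverative_errors <- function(sessions,
                                       crit = criterion_spec("accuracy_pct",
                                                             50, 2)) {
  per <- per_session_choice_stats(sessions)
  hit <- detect_criterion(per$accuracy_pct, crit)
  if (is.na(hit)) {
    return(tibble::tibble(
      sessions_to_criterion = NA_integer_,
      trials_to_criterion = sum(per$n_free),
      errors_to_criterion = sum(per$n_errors),
      perseverative_errors = sum(per$n_errors),
      criterion_met = FALSE))
  }
  first_of_pair <- hit - crit$window + 1L
  before <- per$session_index < per$session_index[first_of_pair]
  through <- seq_len(nrow(per)) <= hit
  tibble::tibble(
    sessions_to_criterion = hit,
    trials_to_criterion = sum(per$n_free[through]),
    errors_to_criterion = sum(per$n_errors[through]),
    perseverative_errors = sum(per$n_errors[before]),
    criterion_met = TRUE)
}

per_session_choice_stats <- function(sessions) {
  if (anyNA(sessions$correct)) {
    abort("choice-task sessions require correct flags on every trial.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(sessions, .data$session_index),
    n_free = sum(!isTRUE_vec(.data$correction_trial)),
    n_errors = sum(!.data$correct & !isTRUE_vec(.data$correction_trial)),
    n_corrections = sum(isTRUE_vec(.data$correction_trial)),
    accuracy_pct = 100 * mean(.data$correct[!isTRUE_vec(.data$correction_trial)]),
    .groups = "drop")
  dplyr::arrange(out, .data$session_index)
}

#' Trials, errors and correction trials to a learning criterion
#'
#' Counts performance through the session at which a consecutive-session
#' accuracy criterion is met. Accuracy denominators exclude correction
#' trials; correction trials are tallied separately when
#' `count_corrections` is set. Animals that never reach criterion within
#' the supplied sessions are flagged `excluded` (the conventional
#' treatment when a session cap elapses).
#'
#' @param sessions Tibble of choice-task trial rows (one animal, ordered
#'   sessions).
#' @param crit A [criterion_spec()]; default accuracy >= 80% on 2
#'   consecutive sessions.
#' @param count_corrections Tally correction trials (default `TRUE`).
#' @return One-row tibble: `sessions_to_criterion`, `trials_to_criterion`,
#'   `errors_to_criterion`, `correction_trials`, `criterion_met`,
#'   `excluded`.
#' @export
trials_errors_to_criterion <- function(sessions,
                                       crit = criterion_spec("accuracy_pct",
                                                             80, 2),
                                       count_corrections = TRUE) {
  per <- per_session_choice_stats(sessions)
  hit <- detect_criterion(per$accuracy_pct, crit)
  through <- if (is.na(hit)) rep(TRUE, nrow(per)) else seq_len(nrow(per)) <= hit
  tibble::tibble(
    sessions_to_criterion = hit,
    trials_to_criterion = sum(per$n_free[through]),
    errors_to_criterion = sum(per$n_errors[through]),
    correction_trials = if (count_corrections)
      sum(per$n_corrections[through]) else NA_integer_,
    criterion_met = !is.na(hit),
    excluded = is.na(hit))
}

#' Reversal summaries across a cohort
#'
#' @param cohort A [cohort_table()].
#' @param acq_crit,rev_crit Criteria for acquisition (80%/2) and reversal
#'   (50%/2).
#' @return Tibble with one row per animal: acquisition counts
#'   (`vd_*`), reversal counts (`rev_*`) and `perseverative_errors`.
#' @export
summarize_vdr_cohort <- function(cohort,
                                 acq_crit = criterion_spec("accuracy_pct", 80, 2),
                                 rev_crit = criterion_spec("accuracy_pct", 50, 2)) {
  stopifnot(inherits(cohort, "cohort_table"))
  ids <- unique(cohort$trials$animal_id[cohort$trials$task %in% c("VD", "REV")])
  purrr::map_dfr(ids, function(aid) {
    vd <- dplyr::filter(cohort$trials, .data$animal_id == aid,
                        .data$task == "VD")
    rv <- dplyr::filter(cohort$trials, .data$animal_id == aid,
                        .data$task == "REV")
    acq <- trials_errors_to_criterion(vd, acq_crit)
    rev <- count_perseverative_errors(rv, rev_crit)
    tibble::tibble(
      animal_id = aid,
      genotype = vd$genotype[1] %||% rv$genotype[1],
      vd_sessions = acq$sessions_to_criterion,
      vd_trials = acq$trials_to_criterion,
      vd_errors = acq$errors_to_criterion,
      vd_correction_trials = acq$correction_trials,
      vd_excluded = acq$excluded,
      rev_sessions = rev$sessions_to_criterion,
      rev_trials = rev$trials_to_criterion,
      rev_errors = rev$errors_to_criterion,
      perseverative_errors = rev$perseverative_errors,
      rev_criterion_met = rev$criterion_met)
  })
}

#' Pairwise Pearson correlations per group
#'
#' Computes the pairwise Pearson correlation matrix of a set of
#' per-animal measures, separately within each genotype group (the
#' standard group-split heatmap), with pairwise deletion of missing
#' values. Pairs involving a constant column are undefined and reported
#' as `NA`.
#'
#' @param measures Tibble of per-animal measures; must contain `genotype`
#'   plus numeric measure columns (an `animal_id` column is ignored).
#' @param by_group Split by genotype (default `TRUE`); if `FALSE` one
#'   pooled matrix is returned under the name `"all"`.
#' @return Named list of symmetric correlation matrices with unit
#'   diagonal.
#' @export
correlation_heatmap <- function(measures, by_group = TRUE) {
  num <- measures[setdiff(names(measures), c("animal_id", "genotype"))]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    abort("all measure columns must be numeric.")
  }
  split_idx <- if (by_group) split(seq_len(nrow(measures)),
                                   measures$genotype)
               else list(all = seq_len(nrow(measures)))
  lapply(split_idx, function(idx) {
    if (length(idx) < 3) abort("need at least 3 animals per group.")
    m <- suppressWarnings(
      cor(as.matrix(num[idx, , drop = FALSE]),
          use = "pairwise.complete.obs", method = "pearson"))
    diag(m) <- 1
    m
  })
}
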