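#' Schedule specification
#'
#' A `schedule_spec` captures the structural rules of one touchscreen task:
#' the response requirement and how it grows (fixed ratio versus a linear
#' `+n` progressive ratio), the inactivity rule that terminates a session,
#' session/trial caps, the inter-trial interval, and task-specific fields
#' (extinction stimulus window, reinstatement reward limit).
#'
#' @param kind One of `"FR"`, `"PR"`, `"EXT"`, `"VD"`, `"REV"`,
#'   `"REINSTATE"`, `"FR1_UNCAPPED"`.
#' @param step_n For PR, the linear increment added to the requirement after
#'   each completed trial; for FR, the fixed requirement itself.
#' @param start_req Requirement of the first trial (default 1).
#' @param inactivity_timeout_s A session ends when no screen response or
#'   magazine entry occurs for this many seconds (default 300, i.e. 5 min).
#' @param session_cap_s Hard session duration cap in seconds.
#' @param trial_cap Maximum number of trials, or `Inf` for uncapped tasks.
#' @param iti_s Inter-trial interval in seconds.
#' @param stimulus_duration_s Extinction only: seconds the stimulus stays on
#'   screen before the trial is scored as an omission.
#' @param rewarded_trials_limit Reinstatement only: number of initial trials
#'   that still deliver reward.
#'
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(kind,
                          step_n = 1L,
                          start_req = 1L,
                          inactivity_timeout_s = 300,
                          session_cap_s = 3600,
                          trial_cap = Inf,
                          iti_s = 5,
                          stimulus_duration_s = NA_real_,
                          rewarded_trials_limit = NA_integer_) {
  kinds <- c("FR", "FR1_UNCAPPED", "PR", "EXT", "VD", "REV", "REINSTATE")
  kind <- match.arg(kind, kinds)
  if (kind == "PR" && step_n < 1) {
    abort("PR schedules require step_n >= 1.")
  }
  if (inactivity_timeout_s <= 0) abort("inactivity_timeout_s must be > 0.")
  if (iti_s < 0) abort("iti_s must be >= 0.")
  structure(
    list(
      kind = kind,
      step_n = as.integer(step_n),
      start_req = as.integer(start_req),
      inactivity_timeout_s = inactivity_timeout_s,
      session_cap_s = session_cap_s,
      trial_cap = trial_cap,
      iti_s = iti_s,
      stimulus_duration_s = stimulus_duration_s,
      rewarded_trials_limit = rewarded_trials_limit
    ),
    class = "schedule_spec"
  )
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat("<schedule_spec>", x$kind,
      if (x$kind == "PR") sprintf("(+%d from %d)", x$step_n, x$start_req)
      else if (x$kind %in% c("FR", "REINSTATE")) sprintf("(FR%d)", x$step_n),
      "\n")
  invisible(x)
}

#' Named schedule presets
#'
#' Presets for the standard touchscreen battery. FR1 training targets 30
#' trials in a 30-min session; the condensed retraining variant used before
#' extinction targets 30 FR1 trials in 12.5 min. Progressive ratios PR4,
#' PR8 and PR12 step the requirement by +4, +8 and +12 per completed trial
#' from a starting requirement of 1 and terminate after 5 min of
#' inactivity. Extinction sessions present 30 trials of a 10-s stimulus
#' with a 4.5-s ITI and no reward; reinstatement is an FR1-like 30-trial,
#' 12.5-min session in which only the first three responses are rewarded.
#'
#' @param name One of `"fr1"`, `"fr1_fast"`, `"fr1_uncapped"`, `"fr3"`,
#'   `"fr5"`, `"pr4"`, `"pr8"`, `"pr12"`, `"ext"`, `"vd"`, `"rev"`,
#'   `"reinstate"`.
#' @return A [schedule_spec()].
#' @export
schedule_preset <- function(name) {
  name <- match.arg(tolower(name),
                    c("fr1", "fr1_fast", "fr1_uncapped", "fr3", "fr5",
                      "pr4", "pr8", "pr12", "ext", "vd", "rev", "reinstate"))
  switch(name,
    fr1 = schedule_spec("FR", step_n = 1, trial_cap = 30, session_cap_s = 1800),
    fr1_fast = schedule_spec("FR", step_n = 1, trial_cap = 30, session_cap_s = 750),
    fr1_uncapped = schedule_spec("FR1_UNCAPPED", step_n = 1, trial_cap = Inf,
                                 session_cap_s = 3600),
    fr3 = schedule_spec("FR", step_n = 3, trial_cap = 30, session_cap_s = 1800),
    fr5 = schedule_spec("FR", step_n = 5, trial_cap = 30, session_cap_s = 1800),
    pr4 = schedule_spec("PR", step_n = 4),
    pr8 = schedule_spec("PR", step_n = 8),
    pr12 = schedule_spec("PR", step_n = 12),
    ext = schedule_spec("EXT", trial_cap = 30, iti_s = 4.5,
                        stimulus_duration_s = 10, session_cap_s = 1800),
    vd = schedule_spec("VD", trial_cap = 30, session_cap_s = 3600),
    rev = schedule_spec("REV", trial_cap = 30, session_cap_s = 3600),
    reinstate = schedule_spec("REINSTATE", step_n = 1, trial_cap = 30,
                              session_cap_s = 750, rewarded_trials_limit = 3L)
  )
}

#' Progressive-ratio requirement at a trial
#'
#' Under a linear `+n` progressive ratio the target-response requirement of
#' trial `k` is `start_req + step_n * (k - 1)`; PR4 therefore demands
#' 1, 5, 9, 13, ... responses on successive trials.
#'
#' @param spec A PR [schedule_spec()].
#' @param trial_index 1-based trial index (vectorised).
#' @return Integer requirement(s).
#' @export
#' @examples
#' pr_requirement(schedule_preset("pr4"), 1:4) # 1 5 9 13
pr_requirement <- function(spec, trial_index) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (spec$kind != "PR") abort("pr_requirement() needs a PR schedule_spec.")
  if (any(trial_index < 1)) abort("trial_index must be >= 1.")
  as.integer(spec$start_req + spec$step_n * (trial_index - 1))
}

#' Breakpoint of a progressive-ratio session
#'
#' The breakpoint is the number of target responses emitted in the last
#' successfully completed trial of a PR session — the canonical readout of
#' how hard an animal will work for reward. A session with no completed
#' trial has breakpoint 0.
#'
#' @param session A tibble of trial rows for one PR session, with columns
#'   `requirement` and `n_target_touches` in trial order.
#' @return Integer breakpoint.
#' @export
breakpoint <- function(session) {
  if (!all(c("requirement", "n_target_touches") %in% names(session))) {
    abort("session must have columns requirement and n_target_touches.")
  }
  if ("task" %in% names(session) &&
      nrow(session) > 0 && !all(session$task == "PR")) {
    abort("breakpoint() is defined for PR sessions only.")
  }
  completed <- which(session$n_target_touches == session$requirement)
  if (length(completed) == 0L) return(0L)
  as.integer(session$requirement[max(completed)])
}

#' Session termination time under the inactivity rule
#'
#' Given the ordered times (seconds, session-relative) of all activity
#' events (screen touches and magazine entries), returns the time at which
#' the session ends: the first instant at which no activity has occurred
#' for `inactivity_timeout_s` seconds, or `session_cap_s` if the subject
#' never goes inactive that long.
#'
#' @param event_times_s Non-decreasing numeric vector of activity times.
#' @param spec A [schedule_spec()].
#' @return Termination time in seconds.
#' @export
session_terminated_at <- function(event_times_s, spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (is.unsorted(event_times_s)) abort("event_times_s must be non-decreasing.")
  timeout <- spec$inactivity_timeout_s
  cap <- spec$session_cap_s
  times <- c(0, event_times_s)
  gaps <- diff(c(times, cap + timeout + 1))
  idx <- which(gaps > timeout)
  if (length(idx) == 0L) return(cap)
  min(times[idx[1]] + timeout, cap)
}

#' Criterion specification
#'
#' Performance criteria are expressed as "at least `threshold_pct`% on
#' `window` consecutive sessions": 80% accuracy over 2 sessions for visual
#' discrimination acquisition, 50% accuracy over 2 sessions for reversal,
#' and 77% omissions over 2 sessions for extinction.
#'
#' @param measure `"accuracy_pct"` or `"omission_pct"`.
#' @param threshold_pct Threshold percentage in (0, 100].
#' @param window Number of consecutive qualifying sessions (default 2).
#' @return A `criterion_spec` object.
#' @export
criterion_spec <- function(measure = c("accuracy_pct", "omission_pct"),
                           threshold_pct, window = 2L) {
  measure <- match.arg(measure)
  if (threshold_pct <= 0 || threshold_pct > 100) {
    abort("threshold_pct must be in (0, 100].")
  }
  if (window < 1) abort("window must be >= 1.")
  structure(list(measure = measure, threshold_pct = threshold_pct,
                 window = as.integer(window), direction = "at_least"),
            class = "criterion_spec")
}

#' Detect a consecutive-session criterion
#'
#' Scans a per-session measure series (percent) for the first run of
#' `window` consecutive sessions all at or above the threshold, and returns
#' the index of the *last* session of that run — the session at which the
#' criterion becomes true, so that sessions-to-criterion equals the return
#' value. Returns `NA` if the criterion is never met.
#'
#' @param series Numeric vector of per-session values in `[0, 100]`.
#' @param crit A [criterion_spec()].
#' @return Integer session index or `NA_integer_`.
#' @export
detect_criterion <- function(series, crit) {
  stopifnot(inherits(crit, "criterion_spec"))
  if (length(series) == 0L) return(NA_integer_)
  if (any(series < 0 | series > 100, na.rm = TRUE)) {
    abort("series values must lie in [0, 100].")
  }
  ok <- !is.na(series) & series >= crit$threshold_pct
  w <- crit$window
  if (length(ok) < w) return(NA_integer_)
  for (i in seq_len(length(ok) - w + 1L)) {
    if (all(ok[i:(i + w - 1L)])) return(i + w - 1L)
  }
  NA_integer_
}

#' Annotate correction trials
#'
#' In discrimination acquisition, an error is followed by correction
#' trials: the same stimulus configuration is re-presented until the
#' subject responds correctly. Correction trials are excluded from
#' accuracy denominators but counted separately. In reversal the policy is
#' disabled so that perseverative responding is measured on free trials.
#'
#' This annotator recomputes the `correction_trial` flag from the sequence
#' of `correct` flags: with the policy enabled, every trial following an
#' incorrect trial is a correction trial until (and including) the next
#' correct response.
#'
#' @param trials Tibble of choice-task trial rows with a logical `correct`
#'   column, in order.
#' @param enabled Logical; apply the policy or clear all flags.
#' @return `trials` with the `correction_trial` column rewritten.
#' @export
apply_correction_policy <- function(trials, enabled) {
  if (!"correct" %in% names(trials) || anyNA(trials$correct)) {
    abort("apply_correction_policy() needs choice trials with correct flags.")
  }
  n <- nrow(trials)
  flag <- logical(n)
  if (enabled && n > 1L) {
    in_correction <- FALSE
    for (i in seq_len(n)) {
      flag[i] <- in_correction
      if (in_correction) {
        if (trials$correct[i]) in_correction <- FALSE
      } else if (!trials$correct[i]) {
        in_correction <- TRUE
      }
    }
  }
  trials$correction_trial <- flag
  trials
}

#' Session accuracy excluding correction trials
#'
#' @param trials Tibble with `correct` and `correction_trial` columns.
#' @return Percent correct over non-correction trials (`NaN` if none).
#' @export
session_accuracy <- function(trials) {
  free <- trials[!isTRUE_vec(trials$correction_trial), , drop = FALSE]
  100 * mean(free$correct)
}

isTRUE_vec <- function(x) !is.na(x) & x
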