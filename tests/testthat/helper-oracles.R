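# Independent brute-force oracles and in-code fixtures shared across tests.

# Replay oracle for the PR breakpoint: walk trials in order and remember the
# requirement of the last one whose touch count met its requirement.
oracle_breakpoint <- function(requirement, n_target_touches) {
  bp <- 0L
  for (i in seq_along(requirement)) {
    if (n_target_touches[i] == requirement[i]) bp <- requirement[i]
  }
  as.integer(bp)
}

# Exhaustive-window oracle for consecutive-session criteria.
oracle_detect_criterion <- function(series, threshold, window) {
  n <- length(series)
  if (n < window) return(NA_integer_)
  for (last in window:n) {
    win <- series[(last - window + 1L):last]
    if (all(!is.na(win) & win >= threshold)) return(last)
  }
  NA_integer_
}

# Recount oracle for perseverative errors: independent pass over per-trial
# flags, finding the criterion pair by direct accuracy computation.
oracle_perseverative <- function(session_list, threshold = 50, window = 2) {
  acc <- vapply(session_list, function(s) {
    free <- !s$correction_trial
    100 * mean(s$correct[free])
  }, numeric(1))
  first_pair <- NA_integer_
  for (i in seq_len(max(0, length(acc) - window + 1L))) {
    if (all(acc[i:(i + window - 1L)] >= threshold)) {
      first_pair <- i
      break
    }
  }
  if (is.na(first_pair)) {
    return(sum(vapply(session_list, function(s)
      sum(!s$correct & !s$correction_trial), integer(1))))
  }
  before <- seq_along(session_list) < first_pair
  sum(vapply(session_list[before], function(s)
    sum(!s$correct & !s$correction_trial), integer(1)))
}

# Random PR-like session table (not via the simulator) for oracle tests.
random_pr_session_tbl <- function() {
  n <- sample(1:12, 1)
  req <- 1L + 4L * (seq_len(n) - 1L)
  touches <- ifelse(runif(n) < 0.7, req, pmax(0L, req - sample(1:5, n, TRUE)))
  tibble::tibble(requirement = req, n_target_touches = as.integer(touches))
}

# Minimal hand-built cohort: 2 animals, one PR4 session of `n_trials` each.
make_fixture_cohort <- function(n_trials = 5L) {
  mk <- function(aid, geno, seed) {
    req <- 1L + 4L * (seq_len(n_trials) - 1L)
    trt <- req * 1.5
    tibble::tibble(
      animal_id = aid, genotype = geno, task = "PR",
      session_index = 1L, schedule_kind = "PR", schedule_step = 4L,
      prefed = FALSE, trial_index = seq_len(n_trials), requirement = req,
      n_target_touches = req, n_blank_touches = 1L,
      response_latency_s = 0.8, trt_s = trt,
      reward_collect_latency_s = 1.4, omitted = FALSE, correct = NA,
      correction_trial = NA, beam_breaks = 120L,
      session_duration_s = 1800)
  }
  animals <- tibble::tibble(
    animal_id = c("WT01", "MUT01"), genotype = c("WT", "MUT"),
    body_weight_g = c(30.5, 29.2), free_intake_ml = c(1.3, 0.8))
  cohort_table(animals, dplyr::bind_rows(mk("WT01", "WT"), mk("MUT01", "MUT")))
}

# Choice-task session table with prescribed per-trial correctness.
make_choice_session <- function(session_index, correct,
                                correction = rep(FALSE, length(correct))) {
  n <- length(correct)
  tibble::tibble(
    animal_id = "a1", genotype = "WT", task = "REV",
    session_index = as.integer(session_index), schedule_kind = "REV",
    schedule_step = 1L, prefed = FALSE, trial_index = seq_len(n),
    requirement = 1L, n_target_touches = 1L, n_blank_touches = 0L,
    response_latency_s = 1.2, trt_s = 1.2,
    reward_collect_latency_s = ifelse(correct, 1.5, NA_real_),
    omitted = FALSE, correct = correct, correction_trial = correction,
    beam_breaks = 60L, session_duration_s = 600)
}

# Extinction session table with prescribed omission pattern (30 trials).
make_ext_session <- function(session_index, responded) {
  stopifnot(length(responded) == 30)
  tibble::tibble(
    animal_id = "a1", genotype = "WT", task = "EXT",
    session_index = as.integer(session_index), schedule_kind = "EXT",
    schedule_step = 1L, prefed = FALSE, trial_index = 1:30,
    requirement = 1L, n_target_touches = as.integer(responded),
    n_blank_touches = 0L,
    response_latency_s = ifelse(responded, 2, NA_real_),
    trt_s = ifelse(responded, 2, NA_real_),
    reward_collect_latency_s = NA_real_, omitted = !responded,
    correct = NA, correction_trial = NA, beam_breaks = 40L,
    session_duration_s = 500)
}
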