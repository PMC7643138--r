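#' Trial-log column schema
#'
#' Canonical column order and types of the tidy trial-log CSV. One row is
#' one trial; session-level fields (schedule, beam breaks, duration,
#' prefeeding flag) are repeated on every row of the session. Absent
#' numeric values (e.g. the total response time of an omitted trial) are
#' empty cells, never 0.
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @export
trial_log_schema <- function() {
  c(animal_id = "character", genotype = "character", task = "character",
    session_index = "integer", schedule_kind = "character",
    schedule_step = "integer", prefed = "logical",
    trial_index = "integer", requirement = "integer",
    n_target_touches = "integer", n_blank_touches = "integer",
    response_latency_s = "double", trt_s = "double",
    reward_collect_latency_s = "double", omitted = "logical",
    correct = "logical", correction_trial = "logical",
    beam_breaks = "integer", session_duration_s = "double")
}

#' An empty trial log with the canonical schema
#'
#' @return Zero-row tibble with the columns of [trial_log_schema()].
#' @export
empty_trial_log <- function() {
  schema <- trial_log_schema()
  cols <- lapply(schema, function(ty) switch(ty,
    character = character(), integer = integer(), double = double(),
    logical = logical()))
  tibble::as_tibble(cols)
}

covariate_schema <- function() {
  c(animal_id = "character", genotype = "character",
    body_weight_g = "double", free_intake_ml = "double")
}

#' Construct a cohort table
#'
#' A `cohort_table` bundles an animal covariate table (one row per animal:
#' genotype, body weight, 60-min free reinforcer intake) with a flat
#' trial-level table (one row per trial across all sessions and tasks).
#'
#' @param animals Tibble with columns `animal_id`, `genotype`,
#'   `body_weight_g`, `free_intake_ml`.
#' @param trials Tibble with the columns of [trial_log_schema()].
#' @param validate Run [validate_cohort()] and abort on violations.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(animals, trials, validate = TRUE) {
  animals <- coerce_schema(tibble::as_tibble(animals), covariate_schema(),
                           "covariates")
  trials <- coerce_schema(tibble::as_tibble(trials), trial_log_schema(),
                          "trial log")
  x <- structure(list(animals = animals, trials = trials),
                 class = "cohort_table")
  if (validate) {
    v <- validate_cohort(x)
    if (nrow(v) > 0) {
      abort(c("cohort_table failed validation:",
              stats::setNames(head(v$message, 5), rep("x", min(5, nrow(v))))))
    }
  }
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d animals, %d trials, tasks: %s\n",
              nrow(x$animals), nrow(x$trials),
              paste(unique(x$trials$task), collapse = ", ")))
  invisible(x)
}

coerce_schema <- function(df, schema, what) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0) {
    abort(sprintf("%s has unknown column(s): %s", what,
                  paste(extra, collapse = ", ")))
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      integer = as.integer(df[[col]]),
      double = as.double(df[[col]]),
      logical = as.logical(df[[col]]))
  }
  df
}

#' Read a cohort from trial-log and covariate CSVs
#'
#' @param trials_path Trial-log CSV (columns of [trial_log_schema()]).
#' @param covariates_path Animal covariate CSV; if `NULL`, a covariate
#'   table with missing weight/intake is derived from the trial log.
#' @param validate Abort on invariant violations (default `TRUE`).
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(trials_path, covariates_path = NULL,
                            validate = TRUE) {
  if (!file.exists(trials_path)) {
    abort(sprintf("trial log not found: %s", trials_path))
  }
  trials <- read_schema_csv(trials_path, trial_log_schema(), "trial log")
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path)) {
      abort(sprintf("covariate file not found: %s", covariates_path))
    }
    animals <- read_schema_csv(covariates_path, covariate_schema(),
                               "covariates")
  } else {
    animals <- dplyr::distinct(trials, .data$animal_id, .data$genotype)
    animals$body_weight_g <- NA_real_
    animals$free_intake_ml <- NA_real_
  }
  cohort_table(animals, trials, validate = validate)
}

read_schema_csv <- function(path, schema, what) {
  readr_types <- c(character = "c", integer = "i", double = "d",
                   logical = "l")
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(names(schema), header)
  if (length(missing) > 0) {
    abort(sprintf("%s %s is missing column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(header, names(schema))
  if (length(extra) > 0) {
    abort(sprintf("%s %s has unknown column(s): %s", what, path,
                  paste(extra, collapse = ", ")))
  }
  spec <- paste(readr_types[schema[header]], collapse = "")
  df <- readr::read_csv(path, col_types = spec, na = "",
                        show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "%s %s: %d parsing problem(s); first at line %d, column %d (%s)",
      what, path, nrow(probs), probs$row[1] + 1L, probs$col[1],
      probs$expected[1]))
  }
  df[names(schema)]
}

#' Write a cohort to trial-log and covariate CSVs
#'
#' Writes the canonical column order with deterministic row ordering
#' (animals by id; trials by animal, task, session, trial index), so that
#' write-read-write round-trips are byte identical.
#'
#' @param cohort A [cohort_table()].
#' @param trials_path,covariates_path Output file paths.
#' @return Invisibly, `trials_path`.
#' @export
write_cohort_csv <- function(cohort, trials_path, covariates_path = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  trials <- dplyr::arrange(cohort$trials, .data$animal_id, .data$task,
                           .data$session_index, .data$trial_index)
  readr::write_csv(trials, trials_path, na = "")
  if (!is.null(covariates_path)) {
    animals <- dplyr::arrange(cohort$animals, .data$animal_id)
    readr::write_csv(animals, covariates_path, na = "")
  }
  invisible(trials_path)
}

#' Validate a cohort against the schema invariants
#'
#' Pure check: returns a tibble of violation reports (empty when the
#' cohort is valid) and never raises. Checked rules include positive
#' durations and requirements, monotone 1-based trial indices, the
#' omission contract (omitted trials have no response time and zero target
#' touches), PR requirements matching the `+n` rule for the session's
#' declared step, correction-trial preconditions, and referential
#' integrity between trials and the animal table.
#'
#' @param cohort A `cohort_table` (or a bare list with `animals`/`trials`).
#' @return Tibble with columns `animal_id`, `task`, `session_index`,
#'   `rule`, `message`.
#' @export
validate_cohort <- function(cohort) {
  animals <- cohort$animals
  trials <- cohort$trials
  out <- list()
  say <- function(animal, task, session, rule, msg) {
    tibble::tibble(animal_id = as.character(animal),
                   task = as.character(task),
                   session_index = as.integer(session),
                   rule = rule, message = msg)
  }

  dup <- animals$animal_id[duplicated(animals$animal_id)]
  for (a in unique(dup)) {
    out[[length(out) + 1L]] <-
      say(a, NA, NA, "unique_animal", sprintf("duplicated animal_id %s", a))
  }
  bad_w <- animals$animal_id[!is.na(animals$body_weight_g) &
                               animals$body_weight_g <= 0]
  for (a in bad_w) {
    out[[length(out) + 1L]] <-
      say(a, NA, NA, "body_weight_positive", sprintf("animal %s: body_weight_g <= 0", a))
  }
  bad_i <- animals$animal_id[!is.na(animals$free_intake_ml) &
                               animals$free_intake_ml < 0]
  for (a in bad_i) {
    out[[length(out) + 1L]] <-
      say(a, NA, NA, "intake_nonnegative", sprintf("animal %s: free_intake_ml < 0", a))
  }

  orphan <- setdiff(unique(trials$animal_id), animals$animal_id)
  for (a in orphan) {
    out[[length(out) + 1L]] <-
      say(a, NA, NA, "animal_exists", sprintf("trials reference unknown animal %s", a))
  }

  if (nrow(trials) > 0) {
    by_session <- dplyr::group_split(
      dplyr::group_by(trials, .data$animal_id, .data$task,
                      .data$session_index))
    for (s in by_session) {
      a <- s$animal_id[1]; tk <- s$task[1]; si <- s$session_index[1]
      rep1 <- function(rule, msg) say(a, tk, si, rule, msg)
      if (anyNA(s$trial_index) || any(diff(s$trial_index) <= 0) ||
          s$trial_index[1] < 1) {
        out[[length(out) + 1L]] <- rep1("trial_index_increasing",
          sprintf("%s %s s%s: trial_index must be >= 1 and strictly increasing", a, tk, si))
      }
      if (any(s$requirement < 1, na.rm = TRUE)) {
        out[[length(out) + 1L]] <- rep1("requirement_positive",
          sprintf("%s %s s%s: requirement < 1", a, tk, si))
      }
      if (any(!is.na(s$trt_s) & s$trt_s <= 0)) {
        out[[length(out) + 1L]] <- rep1("trt_positive",
          sprintf("%s %s s%s: trt_s must be > 0 when present", a, tk, si))
      }
      lat_bad <- any(!is.na(s$response_latency_s) & s$response_latency_s < 0) ||
        any(!is.na(s$reward_collect_latency_s) & s$reward_collect_latency_s < 0)
      if (lat_bad) {
        out[[length(out) + 1L]] <- rep1("latency_nonnegative",
          sprintf("%s %s s%s: negative latency", a, tk, si))
      }
      om <- isTRUE_vec(s$omitted)
      if (any(om & (!is.na(s$trt_s) | s$n_target_touches != 0))) {
        out[[length(out) + 1L]] <- rep1("omitted_contract",
          sprintf("%s %s s%s: omitted trials must have no trt_s and 0 target touches", a, tk, si))
      }
      if (any(is.na(s$session_duration_s)) ||
          any(s$session_duration_s <= 0)) {
        out[[length(out) + 1L]] <- rep1("duration_positive",
          sprintf("%s %s s%s: session_duration_s must be > 0", a, tk, si))
      }
      if (any(s$beam_breaks < 0, na.rm = TRUE)) {
        out[[length(out) + 1L]] <- rep1("beam_breaks_nonnegative",
          sprintf("%s %s s%s: beam_breaks < 0", a, tk, si))
      }
      if (tk == "PR" && !anyNA(s$trial_index)) {
        spec <- schedule_spec("PR", step_n = s$schedule_step[1])
        want <- pr_requirement(spec, s$trial_index)
        if (any(s$requirement != want, na.rm = TRUE)) {
          out[[length(out) + 1L]] <- rep1("pr_requirement_rule",
            sprintf("%s PR s%s: requirement deviates from +%d rule",
                    a, si, s$schedule_step[1]))
        }
      }
      cc <- isTRUE_vec(s$correction_trial)
      if (any(cc)) {
        if (anyNA(s$correct[cc])) {
          out[[length(out) + 1L]] <- rep1("correction_needs_correct",
            sprintf("%s %s s%s: correction trials require a correct flag", a, tk, si))
        } else {
          prev_ok <- vapply(which(cc), function(i) {
            prev <- which(!cc[seq_len(i - 1L)])
            length(prev) > 0 && identical(s$correct[max(prev)], FALSE)
          }, logical(1))
          if (!all(prev_ok)) {
            out[[length(out) + 1L]] <- rep1("correction_after_error",
              sprintf("%s %s s%s: correction trial not preceded by an incorrect free trial", a, tk, si))
          }
        }
      }
    }
    key <- paste(trials$animal_id, trials$task, trials$session_index,
                 trials$trial_index)
    if (anyDuplicated(key)) {
      k <- key[duplicated(key)][1]
      out[[length(out) + 1L]] <-
        say(NA, NA, NA, "unique_trial_key",
            sprintf("duplicated (animal, task, session, trial) key: %s", k))
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(animal_id = character(), task = character(),
                          session_index = integer(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}

#' Extract the trial rows of one session
#'
#' @param cohort A `cohort_table`.
#' @param animal_id,task Animal and task labels.
#' @param session_index Session number (default 1).
#' @return Tibble of trial rows in trial order.
#' @export
session_trials <- function(cohort, animal_id, task, session_index = 1L) {
  dplyr::arrange(
    dplyr::filter(cohort$trials, .data$animal_id == !!animal_id,
                  .data$task == !!task,
                  .data$session_index == !!session_index),
    .data$trial_index)
}
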