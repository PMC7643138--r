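#' Convert total response time to a response rate
#'
#' A trial in which `requirement` target responses were completed in
#' `trt_s` seconds corresponds to a rate of `requirement / (trt_s / 60)`
#' responses per minute.
#'
#' @param requirement Number of target responses demanded (>= 1).
#' @param trt_s Total response time in seconds (> 0). Vectorised.
#' @return Response rate(s) in responses/min.
#' @export
#' @examples
#' trt_to_rate(13, 60) # 13 responses in one minute
trt_to_rate <- function(requirement, trt_s) {
  if (any(requirement < 1)) abort("requirement must be >= 1.")
  if (any(is.na(trt_s)) || any(trt_s <= 0)) {
    abort("trt_s must be present and > 0.")
  }
  requirement / (trt_s / 60)
}

#' Per-trial response-rate series of a session
#'
#' One point per *completed* trial (target touches equal to the
#' requirement, with a recorded total response time); a trailing
#' uncompleted trial contributes no point. `x` is the 1-based trial index
#' and `y` the rate in responses/min.
#'
#' @param session Tibble of one session's trial rows.
#' @return Tibble with columns `x` (trial index) and `y` (responses/min);
#'   zero rows if no trial was completed.
#' @export
session_rate_series <- function(session) {
  done <- !is.na(session$trt_s) &
    session$n_target_touches == session$requirement
  s <- session[done, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(tibble::tibble(x = integer(), y = double()))
  }
  tibble::tibble(x = as.integer(s$trial_index),
                 y = trt_to_rate(s$requirement, s$trt_s))
}

#' Fitting options for the decay model
#'
#' @param min_points Minimum number of completed trials required to
#'   attempt a fit (default 5); with fewer points the fit is refused and
#'   flagged unreliable, mirroring schedules whose sparse data cannot
#'   support the model.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence tolerance on the relative parameter change.
#' @param include_first_latency Whether the recorded total response time
#'   is taken as-is (stimulus onset to requirement completion, the
#'   default) — retained as an explicit knob because vendor logs differ in
#'   whether the pre-first-touch latency is part of the trial clock. When
#'   `FALSE`, the response latency is subtracted from the TRT before rate
#'   conversion (only meaningful in [fit_cohort_decay()]).
#' @param form `"exp"` fits `y = a * exp(-b * x)` so that `a` is literally
#'   the peak (x -> 0) rate; `"power_base"` fits the alternative base-`a`
#'   form `y = a^(-b * x)`. That form pins the curve to 1 at `x = 0` (so
#'   no peak-rate parameter exists) and identifies only the product
#'   `b * log(a)`; the fit therefore estimates that single decay constant
#'   and reports it in the unit-base convention `a = e`.
#' @return A `fit_options` object.
#' @export
fit_options <- function(min_points = 5L, max_iter = 200L, tol = 1e-10,
                        include_first_latency = TRUE,
                        form = c("exp", "power_base")) {
  if (min_points < 3) abort("min_points must be >= 3.")
  if (tol <= 0) abort("tol must be > 0.")
  structure(list(min_points = as.integer(min_points),
                 max_iter = as.integer(max_iter), tol = tol,
                 include_first_latency = include_first_latency,
                 form = match.arg(form)),
            class = "fit_options")
}

decay_fit_result <- function(a = NA_real_, b = NA_real_, sse = NA_real_,
                             n_points = 0L, converged = FALSE,
                             reliable = FALSE, reason = NA_character_) {
  structure(list(a = a, b = b, sse = sse, n_points = as.integer(n_points),
                 converged = converged, reliable = reliable,
                 reason = reason),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$reliable) {
    cat(sprintf("<decay_fit> a = %.3f resp/min, b = %.4f /trial (n = %d, sse = %.3g)\n",
                x$a, x$b, x$n_points, x$sse))
  } else {
    cat(sprintf("<decay_fit> unreliable (%s)\n", x$reason))
  }
  invisible(x)
}

#' Fit the within-session exponential rate-decay model
#'
#' Fits `y = a * exp(-b * x)` to a per-trial rate series by nonlinear
#' least squares (Levenberg–Marquardt), where `a` is the peak response
#' rate (responses/min, the curve's maximum as `x -> 0`) and `b >= 0` the
#' per-trial decay rate. `a` indexes the animal's maximal motivation to
#' respond; `b` how quickly that motivation declines across trials.
#'
#' Starting values come from the log-linear regression of `ln y` on `x`
#' (`a` from the intercept, `b` from the negative slope clamped at 0);
#' `b` is constrained to be non-negative, so a flat series returns the
#' boundary solution `b = 0` with `a` the series mean. Fits on fewer than
#' `min_points` points are refused (returned with `reliable = FALSE` and
#' a recorded reason) rather than attempted — sparse sessions cannot
#' identify the model.
#'
#' @param points Tibble with columns `x` (trial index) and `y`
#'   (responses/min, all > 0), e.g. from [session_rate_series()].
#' @param opts [fit_options()].
#' @return A `decay_fit`: `a`, `b`, `sse`, `n_points`, `converged`,
#'   `reliable`, `reason`.
#' @export
fit_decay <- function(points, opts = fit_options()) {
  stopifnot(inherits(opts, "fit_options"))
  n <- nrow(points)
  if (n < opts$min_points) {
    return(decay_fit_result(n_points = n, reason = sprintf(
      "only %d completed trial(s); %d required", n, opts$min_points)))
  }
  if (any(points$y <= 0)) {
    return(decay_fit_result(n_points = n,
                            reason = "non-positive rate value"))
  }
  x <- as.double(points$x)
  y <- as.double(points$y)
  ll <- lm(log(y) ~ x)
  a0 <- exp(unname(coef(ll)[1]))
  b0 <- max(0, -unname(coef(ll)[2]))
  # data lying exactly on a (possibly flat) decay curve: the log-linear
  # solution is already the least-squares optimum, and the iterative
  # optimizer has a zero gradient to work with
  if (opts$form == "exp" && unname(coef(ll)[2]) <= 1e-12 &&
      sum(stats::residuals(ll)^2) < 1e-18) {
    sse0 <- sum((y - a0 * exp(-b0 * x))^2)
    return(decay_fit_result(a = a0, b = b0, sse = sse0, n_points = n,
                            converged = TRUE, reliable = TRUE))
  }
  fit <- tryCatch(
    if (opts$form == "exp") {
      minpack.lm::nlsLM(
        y ~ a * exp(-b * x), start = list(a = a0, b = b0),
        lower = c(a = 1e-12, b = 0), upper = c(a = Inf, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                             ftol = opts$tol,
                                             ptol = opts$tol))
    } else {
      # the base-a form a^(-b*x) pins y(0) = 1 and identifies only the
      # product b*log(a); the identifiable decay constant is estimated
      # and reported in the unit-base convention a = e, b = c
      minpack.lm::nlsLM(
        y ~ exp(-cc * x), start = list(cc = max(b0, 1e-8)),
        lower = c(cc = 0),
        control = minpack.lm::nls.lm.control(maxiter = opts$max_iter,
                                             ftol = opts$tol,
                                             ptol = opts$tol))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(decay_fit_result(n_points = n, converged = FALSE,
                            reason = conditionMessage(fit)))
  }
  est <- coef(fit)
  if (opts$form == "power_base") {
    est <- c(a = exp(1), b = unname(est[["cc"]]))
  }
  sse <- sum(stats::resid(fit)^2)
  converged <- fit$convInfo$isConv %||% TRUE
  reliable <- isTRUE(converged) && n >= opts$min_points &&
    is.finite(est[["b"]]) && is.finite(est[["a"]])
  decay_fit_result(a = unname(est[["a"]]), b = unname(est[["b"]]),
                   sse = sse, n_points = n, converged = isTRUE(converged),
                   reliable = reliable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the decay model across a cohort
#'
#' Builds the per-trial rate series of every selected session and fits
#' [fit_decay()] per animal per session. Unreliable fits (too few
#' completed trials, non-convergence) are flagged, never dropped
#' silently; downstream group comparisons exclude them by default.
#'
#' @param cohort A [cohort_table()].
#' @param task Task label selecting the sessions (e.g. `"PR"`,
#'   `"FR1_UNCAPPED"`).
#' @param session_index Optional filter on the session number; `NULL`
#'   (default) fits every selected session.
#' @param schedule_step Optional filter on the schedule step (e.g. 4 for
#'   PR4 when several PR schedules share the `"PR"` task label).
#' @param prefed Filter on the prefeeding flag; the default `FALSE`
#'   restricts the rate analysis to non-prefed sessions, where the decay
#'   profile is uncontaminated by satiety. `NULL` disables the filter.
#' @param opts [fit_options()].
#' @return Tibble with one row per fitted session: `animal_id`,
#'   `genotype`, `task`, `schedule_step`, `session_index`, `a`, `b`,
#'   `sse`, `n_points`, `converged`, `reliable`, `exclusion_reason`.
#' @export
fit_cohort_decay <- function(cohort, task = "PR", session_index = NULL,
                             schedule_step = NULL, prefed = FALSE,
                             opts = fit_options()) {
  stopifnot(inherits(cohort, "cohort_table"))
  trials <- dplyr::filter(cohort$trials, .data$task == !!task)
  if (!is.null(session_index)) {
    trials <- dplyr::filter(trials, .data$session_index == !!session_index)
  }
  if (!is.null(schedule_step)) {
    trials <- dplyr::filter(trials, .data$schedule_step == !!schedule_step)
  }
  if (!is.null(prefed)) {
    trials <- dplyr::filter(trials, .data$prefed == !!prefed)
  }
  if (nrow(trials) == 0L) {
    return(tibble::tibble(animal_id = character(), genotype = character(),
                          task = character(), schedule_step = integer(),
                          session_index = integer(), a = double(),
                          b = double(), sse = double(), n_points = integer(),
                          converged = logical(), reliable = logical(),
                          exclusion_reason = character()))
  }
  groups <- dplyr::group_split(
    dplyr::group_by(trials, .data$animal_id, .data$session_index))
  purrr::map_dfr(groups, function(s) {
    pts <- session_rate_series(s)
    if (!opts$include_first_latency && nrow(pts) > 0) {
      done <- !is.na(s$trt_s) & s$n_target_touches == s$requirement
      adj <- s$trt_s[done] - dplyr::coalesce(s$response_latency_s[done], 0)
      keep <- adj > 0
      pts <- tibble::tibble(x = pts$x[keep],
                            y = trt_to_rate(s$requirement[done][keep],
                                            adj[keep]))
    }
    f <- fit_decay(pts, opts)
    tibble::tibble(
      animal_id = s$animal_id[1], genotype = s$genotype[1],
      task = s$task[1], schedule_step = s$schedule_step[1],
      session_index = s$session_index[1],
      a = f$a, b = f$b, sse = f$sse, n_points = f$n_points,
      converged = f$converged, reliable = f$reliable,
      exclusion_reason = if (f$reliable) NA_character_ else f$reason)
  })
}
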