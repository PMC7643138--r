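#' Agent parameters for the cohort simulator
#'
#' The simulator is a stochastic agent whose responding is governed by a
#' small set of interpretable parameters:
#'
#' * `peak_rate_A` — true peak response rate (responses/min), the agent's
#'   maximum (activational) motivation at the start of a session.
#' * `decay_B` — per-trial exponential decay of the latent response rate,
#'   i.e. how fast motivation wanes within a session.
#' * `persev_rho` — perseveration, in `[0, 1)`. It damps the effective
#'   decay when reinforcement is sparse (so a perseverative agent keeps
#'   responding under lean schedules) and adds choice stickiness toward
#'   the previously preferred stimulus in reversal.
#' * `init_deficit_eps` — initiation deficit (>= 0): elevates omission
#'   probability and response latency over roughly the first three trials
#'   of each session, the signature of activational apathy.
#' * `learn_alpha` — learning rate in `(0, 1]` for choice value updates
#'   and for the decline of the extinction response drive.
#' * `noise_sigma` — lognormal sd of the per-trial latent rate. When 0 the
#'   generator runs in a fully deterministic degenerate mode (all latent
#'   draws collapse to their means), which is what makes closed-form
#'   recovery checks possible.
#' * `omission_base` — baseline omission probability in extinction.
#' * `collect_latency_mu_s` — mean reward-collection latency (s).
#' * `blank_rate` — expected blank (off-target) touches per trial.
#' * `intake_mu_ml`, `intake_sd_ml` — 60-min free-intake distribution.
#' * `weight_mu_g`, `weight_sd_g` — body-weight distribution.
#'
#' @param peak_rate_A,decay_B,persev_rho,init_deficit_eps,learn_alpha
#'   Core motivation/learning parameters, see Details.
#' @param noise_sigma,omission_base,collect_latency_mu_s,blank_rate
#'   Nuisance process parameters.
#' @param intake_mu_ml,intake_sd_ml,weight_mu_g,weight_sd_g Covariate
#'   distributions.
#' @return An `agent_params` object.
#' @export
agent_params <- function(peak_rate_A = 100, decay_B = 0.25,
                         persev_rho = 0.15, init_deficit_eps = 0.15,
                         learn_alpha = 0.35, noise_sigma = 0.15,
                         omission_base = 0.05, collect_latency_mu_s = 1.5,
                         blank_rate = 1.5, intake_mu_ml = 1.2,
                         intake_sd_ml = 0.25, weight_mu_g = 30,
                         weight_sd_g = 2.5) {
  p <- list(peak_rate_A = peak_rate_A, decay_B = decay_B,
            persev_rho = persev_rho, init_deficit_eps = init_deficit_eps,
            learn_alpha = learn_alpha, noise_sigma = noise_sigma,
            omission_base = omission_base,
            collect_latency_mu_s = collect_latency_mu_s,
            blank_rate = blank_rate, intake_mu_ml = intake_mu_ml,
            intake_sd_ml = intake_sd_ml, weight_mu_g = weight_mu_g,
            weight_sd_g = weight_sd_g)
  if (p$peak_rate_A <= 0) abort("peak_rate_A must be > 0.")
  if (p$decay_B < 0) abort("decay_B must be >= 0.")
  if (p$persev_rho < 0 || p$persev_rho >= 1) {
    abort("persev_rho must be in [0, 1).")
  }
  if (p$init_deficit_eps < 0) abort("init_deficit_eps must be >= 0.")
  if (p$learn_alpha <= 0 || p$learn_alpha > 1) {
    abort("learn_alpha must be in (0, 1].")
  }
  if (p$noise_sigma < 0) abort("noise_sigma must be >= 0.")
  if (p$omission_base < 0 || p$omission_base > 1) {
    abort("omission_base must be in [0, 1].")
  }
  structure(p, class = "agent_params")
}

#' Genotype presets
#'
#' Two shipped presets give cohorts the qualitative contrast between a
#' wild-type-like group and a mutant-like group: the mutant preset has a
#' lower peak rate and slower within-session decay, stronger
#' perseveration, a stronger initiation deficit, a lower learning rate and
#' lower free reinforcer intake. The numeric values are illustrative
#' calibrations chosen to produce realistic touchscreen sessions; they are
#' not estimates from any real cohort.
#'
#' @param name `"WT"` or `"MUT"`.
#' @return A list with elements `name` and `params` ([agent_params()]).
#' @export
genotype_preset <- function(name = c("WT", "MUT")) {
  name <- match.arg(name)
  params <- switch(name,
    WT = agent_params(),
    MUT = agent_params(peak_rate_A = 70, decay_B = 0.15, persev_rho = 0.45,
                       init_deficit_eps = 0.6, learn_alpha = 0.18,
                       intake_mu_ml = 0.9))
  list(name = name, params = params)
}

#' Simulation configuration
#'
#' @param seed Master seed; all per-animal and per-task random streams are
#'   derived from it deterministically, so a fixed config yields bit-equal
#'   cohorts.
#' @param n_per_group Animals per genotype preset (default 16).
#' @param tasks Character vector of battery components, any of `"pr4"`,
#'   `"pr4_prefed"`, `"pr8"`, `"pr12"`, `"fr1_uncapped"`, `"ext"`,
#'   `"reinstate"`, `"vd_rev"`.
#' @param ext_sessions_max,acq_sessions_max,rev_sessions_max Session caps
#'   for extinction, discrimination acquisition and reversal.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L, n_per_group = 16L,
                       tasks = c("pr4", "pr4_prefed", "pr8", "pr12",
                                 "fr1_uncapped", "ext", "reinstate",
                                 "vd_rev"),
                       ext_sessions_max = 20L, acq_sessions_max = 20L,
                       rev_sessions_max = 30L) {
  known <- c("pr4", "pr4_prefed", "pr8", "pr12", "fr1_uncapped", "ext",
             "reinstate", "vd_rev")
  bad <- setdiff(tasks, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown task(s): %s", paste(bad, collapse = ", ")))
  }
  if (n_per_group < 1) abort("n_per_group must be >= 1.")
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 tasks = tasks, ext_sessions_max = as.integer(ext_sessions_max),
                 acq_sessions_max = as.integer(acq_sessions_max),
                 rev_sessions_max = as.integer(rev_sessions_max)),
            class = "sim_config")
}

# Counter-based child-seed derivation: a 31-bit affine mix that stays exact
# in double arithmetic, so per-animal/per-task streams are reproducible and
# decoupled from evaluation order.
child_seed <- function(seed, counter) {
  as.integer(((seed %% 2147483647) * 69069 + counter * 12345 + 1) %%
               2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Latent response rate (responses/min) on trial k. Perseveration damps the
# effective decay in proportion to how sparse reinforcement has been.
latent_rate <- function(params, k, reinf_density, det) {
  b_eff <- params$decay_B *
    (1 - params$persev_rho * (1 - reinf_density))
  eta <- if (det) 1 else exp(rnorm(1, 0, params$noise_sigma))
  params$peak_rate_A * exp(-b_eff * k) * eta
}

collect_latency <- function(params, det) {
  mu <- params$collect_latency_mu_s
  shift <- min(0.2, mu / 2)
  if (det) return(mu)
  m <- mu - shift
  sdlog <- 0.3
  shift + stats::rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

blank_touches <- function(params, det) {
  if (det) as.integer(round(params$blank_rate)) else rpois(1, params$blank_rate)
}

init_inflation <- function(params, k) {
  1 + params$init_deficit_eps * exp(-(k - 1) / 3)
}

session_tibble <- function(animal_id, genotype, task, session_index, spec,
                           prefed, rows, duration, det) {
  n <- length(rows$trial_index)
  beam <- if (det) as.integer(round(3 * duration / 60)) else
    rpois(1, 3 * duration / 60)
  tibble::tibble(
    animal_id = animal_id, genotype = genotype, task = task,
    session_index = as.integer(session_index),
    schedule_kind = spec$kind, schedule_step = spec$step_n,
    prefed = prefed,
    trial_index = as.integer(rows$trial_index),
    requirement = as.integer(rows$requirement),
    n_target_touches = as.integer(rows$n_target_touches),
    n_blank_touches = as.integer(rows$n_blank_touches),
    response_latency_s = rows$response_latency_s,
    trt_s = rows$trt_s,
    reward_collect_latency_s = rows$reward_collect_latency_s,
    omitted = rows$omitted,
    correct = rows$correct,
    correction_trial = rows$correction_trial,
    beam_breaks = beam,
    session_duration_s = duration
  )
}

empty_rows <- function() {
  list(trial_index = integer(), requirement = integer(),
       n_target_touches = integer(), n_blank_touches = integer(),
       response_latency_s = double(), trt_s = double(),
       reward_collect_latency_s = double(), omitted = logical(),
       correct = logical(), correction_trial = logical())
}

push_row <- function(rows, trial_index, requirement, n_target_touches,
                     n_blank_touches, response_latency_s, trt_s,
                     reward_collect_latency_s, omitted, correct = NA,
                     correction_trial = NA) {
  rows$trial_index <- c(rows$trial_index, trial_index)
  rows$requirement <- c(rows$requirement, requirement)
  rows$n_target_touches <- c(rows$n_target_touches, n_target_touches)
  rows$n_blank_touches <- c(rows$n_blank_touches, n_blank_touches)
  rows$response_latency_s <- c(rows$response_latency_s, response_latency_s)
  rows$trt_s <- c(rows$trt_s, trt_s)
  rows$reward_collect_latency_s <- c(rows$reward_collect_latency_s,
                                     reward_collect_latency_s)
  rows$omitted <- c(rows$omitted, omitted)
  rows$correct <- c(rows$correct, correct)
  rows$correction_trial <- c(rows$correction_trial, correction_trial)
  rows
}

#' Simulate one ratio-schedule session (PR or FR)
#'
#' The agent's latent response rate on trial `k` is
#' `A * exp(-B_eff * k) * eta`, with lognormal multiplicative noise `eta`
#' and an effective decay `B_eff = B * (1 - rho * (1 - d))` damped by
#' perseveration `rho` when the running reinforcement density `d`
#' (rewards so far per target touch so far) is low. Within a trial,
#' inter-response intervals are exponential with mean `60 / rate` seconds;
#' the initiation deficit inflates the first interval of early trials.
#' The session ends by the 5-min inactivity rule, the session cap, or the
#' trial cap. With `noise_sigma = 0` every draw collapses to its mean and
#' the session is fully deterministic.
#'
#' For fixed-ratio kinds the requirement is constant and the rate decays
#' with rewards earned (satiation) instead of trial number; a
#' reinstatement session rewards only the first `rewarded_trials_limit`
#' completed trials.
#'
#' @param params [agent_params()].
#' @param spec [schedule_spec()] of kind `"PR"` (for
#'   [simulate_pr_session()]) or `"FR"`/`"FR1_UNCAPPED"`/`"REINSTATE"`
#'   (for [simulate_fr_session()]).
#' @param seed Integer seed; identical inputs give identical sessions.
#' @param animal_id,genotype,session_index,prefed Labels stamped on rows.
#' @return Tibble of trial rows in the trial-log schema.
#' @export
simulate_pr_session <- function(params, spec, seed, animal_id = "sim",
                                genotype = "WT", session_index = 1L,
                                prefed = FALSE) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "schedule_spec"))
  if (spec$kind != "PR") abort("simulate_pr_session() needs a PR spec.")
  with_seed(seed, simulate_ratio_session(params, spec, animal_id, genotype,
                                         session_index, prefed))
}

#' @rdname simulate_pr_session
#' @export
simulate_fr_session <- function(params, spec, seed, animal_id = "sim",
                                genotype = "WT", session_index = 1L,
                                prefed = FALSE) {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "schedule_spec"))
  if (!spec$kind %in% c("FR", "FR1_UNCAPPED", "REINSTATE")) {
    abort("simulate_fr_session() needs an FR, FR1_UNCAPPED or REINSTATE spec.")
  }
  with_seed(seed, simulate_ratio_session(params, spec, animal_id, genotype,
                                         session_index, prefed))
}

simulate_ratio_session <- function(params, spec, animal_id, genotype,
                                   session_index, prefed) {
  det <- params$noise_sigma == 0
  timeout <- spec$inactivity_timeout_s
  cap <- spec$session_cap_s
  is_pr <- spec$kind == "PR"
  rows <- empty_rows()
  t <- 0
  k <- 1L
  rewards <- 0L
  touches <- 0L
  end_time <- NULL
  while (k <= spec$trial_cap) {
    req <- if (is_pr) pr_requirement(spec, k) else spec$step_n
    dens <- if (touches == 0L) 1 else rewards / touches
    rate_idx <- if (is_pr) k else rewards
    r <- latent_rate(params, rate_idx, dens, det)
    m <- 60 / r
    # irreducible motor/travel time per touch: intervals are a shifted
    # exponential with unchanged mean, so a single fast draw cannot
    # produce physically impossible instantaneous rates
    floor_t <- min(0.45, 0.35 * m)
    intervals <- if (det) rep(m, req)
                 else floor_t + rexp(req, rate = 1 / (m - floor_t))
    intervals[1] <- intervals[1] * init_inflation(params, k)
    long <- which(intervals > timeout)
    if (length(long) > 0) {
      done <- long[1] - 1L
      touches <- touches + done
      stop_t <- min(t + sum(intervals[seq_len(done)]) + timeout, cap)
      rows <- push_row(rows, k, req, done, blank_touches(params, det),
                       if (done > 0) intervals[1] else NA_real_, NA_real_,
                       NA_real_, omitted = done == 0L)
      end_time <- stop_t
      break
    }
    ends <- t + cumsum(intervals)
    if (ends[req] > cap) {
      done <- sum(ends <= cap)
      touches <- touches + done
      rows <- push_row(rows, k, req, done, blank_touches(params, det),
                       if (done > 0) intervals[1] else NA_real_, NA_real_,
                       NA_real_, omitted = done == 0L)
      end_time <- cap
      break
    }
    trt <- sum(intervals)
    touches <- touches + req
    rewarded <- spec$kind != "REINSTATE" ||
      rewards < spec$rewarded_trials_limit
    cl <- if (rewarded) collect_latency(params, det) else NA_real_
    if (rewarded) rewards <- rewards + 1L
    rows <- push_row(rows, k, req, req, blank_touches(params, det),
                     intervals[1], trt, cl, omitted = FALSE)
    t <- t + trt + (if (rewarded) cl else 0) + spec$iti_s
    if (t >= cap) {
      end_time <- cap
      break
    }
    k <- k + 1L
  }
  if (is.null(end_time)) end_time <- min(t + timeout, cap)
  session_tibble(animal_id, genotype, spec$kind, session_index, spec,
                 prefed, rows, end_time, det)
}

#' Simulate an extinction series
#'
#' During extinction the stimulus is presented for
#' `stimulus_duration_s` seconds and touching it yields no reward. The
#' agent's probability of responding on trial `k` of session `s` is
#' `(1 - omission_base) * plogis(theta_s) * (1 - eps_k)`, where the
#' response drive `theta` declines after each non-rewarded response at a
#' speed set by `learn_alpha`, and the initiation factor
#' `eps_k = init_deficit_eps * exp(-k / 3)` inflates omissions over the
#' first few trials of every session. The series stops when omissions
#' reach at least 77% in two consecutive sessions (the extinction
#' criterion) or after `n_sessions_max` sessions.
#'
#' @param params [agent_params()].
#' @param spec An EXT [schedule_spec()].
#' @param n_sessions_max Maximum number of sessions.
#' @param seed Integer seed.
#' @param animal_id,genotype Labels stamped on rows.
#' @return Tibble of trial rows covering all simulated sessions.
#' @export
simulate_extinction_series <- function(params, spec, n_sessions_max, seed,
                                       animal_id = "sim", genotype = "WT") {
  stopifnot(inherits(params, "agent_params"), inherits(spec, "schedule_spec"))
  if (spec$kind != "EXT") abort("simulate_extinction_series() needs an EXT spec.")
  with_seed(seed, {
    det <- params$noise_sigma == 0
    crit <- criterion_spec("omission_pct", 77, window = 2)
    n_tr <- spec$trial_cap
    theta <- 2.5
    out <- vector("list", n_sessions_max)
    omission_pct <- numeric(0)
    for (s in seq_len(n_sessions_max)) {
      k <- seq_len(n_tr)
      eps_k <- pmin(1, params$init_deficit_eps * exp(-k / 3))
      p <- (1 - params$omission_base) * plogis(theta) * (1 - eps_k)
      responded <- if (det) p >= 0.5 else runif(n_tr) < p
      lat_base <- if (det) rep(1.5, n_tr) else stats::rlnorm(n_tr, log(1.5), 0.4)
      lat <- ifelse(responded,
                    pmin(lat_base * (1 + eps_k),
                         spec$stimulus_duration_s * 0.99),
                    NA_real_)
      rows <- list(
        trial_index = seq_len(n_tr),
        requirement = rep(1L, n_tr),
        n_target_touches = as.integer(responded),
        n_blank_touches = if (det) rep(as.integer(round(params$blank_rate)), n_tr)
                          else rpois(n_tr, params$blank_rate),
        response_latency_s = lat,
        trt_s = lat,
        reward_collect_latency_s = rep(NA_real_, n_tr),
        omitted = !responded,
        correct = rep(NA, n_tr),
        correction_trial = rep(NA, n_tr)
      )
      duration <- sum(ifelse(responded, lat, spec$stimulus_duration_s)) +
        n_tr * spec$iti_s
      out[[s]] <- session_tibble(animal_id, genotype, "EXT", s, spec,
                                 FALSE, rows, duration, det)
      theta <- theta - params$learn_alpha * 0.1 * sum(responded)
      omission_pct <- c(omission_pct, 100 * mean(!responded))
      if (!is.na(detect_criterion(omission_pct, crit))) break
    }
    dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  })
}

#' Simulate a visual discrimination + reversal series
#'
#' A two-alternative value-learning agent: stimulus values `Q` are updated
#' with learning rate `learn_alpha` on each outcome, and the probability
#' of choosing stimulus 1 is `plogis(4 * (Q1 - Q2 + rho * pref))`, where
#' `pref` is an exponentially weighted trace of recent choices and `rho`
#' (the perseveration parameter) weights that stickiness. Acquisition runs
#' 30 free trials per session with correction trials after errors
#' (re-presenting the failed configuration until a correct response;
#' corrections are excluded from accuracy), until accuracy reaches 80% on
#' two consecutive sessions or `acq_sessions_max` sessions elapse. The
#' reward contingency then reverses and sessions continue without
#' correction trials until accuracy recovers to 50% on two consecutive
#' sessions or `rev_sessions_max` sessions elapse. The initiation deficit
#' inflates response latencies on the first trials of each session.
#'
#' @param params [agent_params()].
#' @param acq_spec,rev_spec `VD` and `REV` [schedule_spec()]s.
#' @param seed Integer seed.
#' @param acq_sessions_max,rev_sessions_max Session caps.
#' @param animal_id,genotype Labels stamped on rows.
#' @return Tibble of trial rows; acquisition sessions carry task `"VD"`,
#'   reversal sessions task `"REV"`.
#' @export
simulate_vdr_series <- function(params, acq_spec, rev_spec, seed,
                                acq_sessions_max = 20L,
                                rev_sessions_max = 30L,
                                animal_id = "sim", genotype = "WT") {
  stopifnot(inherits(params, "agent_params"))
  if (acq_spec$kind != "VD" || rev_spec$kind != "REV") {
    abort("simulate_vdr_series() needs a VD spec and a REV spec.")
  }
  with_seed(seed, {
    state <- new.env(parent = emptyenv())
    state$q1 <- 0.2
    state$q2 <- 0.2
    state$pref <- 0
    acq <- simulate_choice_phase(params, acq_spec, state, rewarded_stim = 1L,
                                 corrections = TRUE,
                                 crit = criterion_spec("accuracy_pct", 80, 2),
                                 max_sessions = acq_sessions_max,
                                 animal_id = animal_id, genotype = genotype)
    rev <- simulate_choice_phase(params, rev_spec, state, rewarded_stim = 2L,
                                 corrections = FALSE,
                                 crit = criterion_spec("accuracy_pct", 50, 2),
                                 max_sessions = rev_sessions_max,
                                 animal_id = animal_id, genotype = genotype)
    dplyr::bind_rows(acq, rev)
  })
}

simulate_choice_phase <- function(params, spec, state, rewarded_stim,
                                  corrections, crit, max_sessions,
                                  animal_id, genotype) {
  det <- params$noise_sigma == 0
  beta <- 5
  tau <- 0.2
  max_corrections <- 15L
  n_free <- spec$trial_cap
  out <- vector("list", max_sessions)
  acc <- numeric(0)
  for (s in seq_len(max_sessions)) {
    rows <- empty_rows()
    idx <- 0L
    n_correct_free <- 0L
    duration <- 0
    for (k in seq_len(n_free)) {
      res <- simulate_choice_trial(params, state, rewarded_stim, beta, tau,
                                   k, det)
      idx <- idx + 1L
      rows <- push_row(rows, idx, 1L, 1L, blank_touches(params, det),
                       res$lat, res$lat,
                       if (res$correct) collect_latency(params, det) else NA_real_,
                       omitted = FALSE, correct = res$correct,
                       correction_trial = FALSE)
      duration <- duration + res$lat + spec$iti_s
      if (res$correct) {
        n_correct_free <- n_correct_free + 1L
      } else if (corrections) {
        for (cti in seq_len(max_corrections)) {
          res_c <- simulate_choice_trial(params, state, rewarded_stim, beta,
                                         tau, k, det)
          idx <- idx + 1L
          rows <- push_row(rows, idx, 1L, 1L, blank_touches(params, det),
                           res_c$lat, res_c$lat,
                           if (res_c$correct) collect_latency(params, det)
                           else NA_real_,
                           omitted = FALSE, correct = res_c$correct,
                           correction_trial = TRUE)
          duration <- duration + res_c$lat + spec$iti_s
          if (res_c$correct) break
        }
      }
    }
    out[[s]] <- session_tibble(animal_id, genotype, spec$kind, s, spec,
                               FALSE, rows, duration, det)
    acc <- c(acc, 100 * n_correct_free / n_free)
    if (!is.na(detect_criterion(acc, crit))) break
  }
  dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
}

simulate_choice_trial <- function(params, state, rewarded_stim, beta, tau,
                                  k, det) {
  # 8% lapse rate keeps asymptotic accuracy off the ceiling, as in real
  # touchscreen discrimination data
  lapse <- 0.08
  p1 <- lapse / 2 + (1 - lapse) *
    plogis(beta * ((state$q1 - state$q2) + params$persev_rho * state$pref))
  # choice sampling is intrinsic to the agent, not magnitude noise, so it
  # stays stochastic even in the deterministic-rate mode
  choice <- if (runif(1) < p1) 1L else 2L
  correct <- choice == rewarded_stim
  reward <- as.numeric(correct)
  # per-trial value steps are a scaled-down learn_alpha (0.25x) so that
  # acquisition spans several sessions, not trials; unlearning from non-reward is
  # slower again (0.3x) — the asymmetry that lets a previously reinforced
  # choice persist after the contingency flips
  alpha_c <- 0.15 * params$learn_alpha
  alpha <- if (correct) alpha_c else 0.3 * alpha_c
  if (choice == 1L) {
    state$q1 <- state$q1 + alpha * (reward - state$q1)
    state$pref <- (1 - tau) * state$pref + tau
  } else {
    state$q2 <- state$q2 + alpha * (reward - state$q2)
    state$pref <- (1 - tau) * state$pref - tau
  }
  base_lat <- if (det) 1.8 else stats::rlnorm(1, log(1.8), 0.35)
  list(correct = correct, lat = base_lat * init_inflation(params, k))
}

#' Simulate a full cohort
#'
#' Generates `n_per_group` animals per genotype preset, draws their
#' covariates (body weight, 60-min free intake) from the preset
#' distributions, and runs each animal through the configured battery.
#' Child seeds are derived from `config$seed` with a counter-based mix, so
#' identical configs give bit-identical cohorts and each animal's stream
#' is independent of the others.
#'
#' The optional prefed PR4 component models prefeeding (60 min of free
#' reinforcer access before the session) by scaling the peak rate down to
#' 55% and lengthening reward-collection latencies, the standard satiety
#' signature.
#'
#' @param config A [sim_config()].
#' @param presets List of presets from [genotype_preset()].
#' @return A validated [cohort_table()].
#' @export
simulate_cohort <- function(config,
                            presets = list(genotype_preset("WT"),
                                           genotype_preset("MUT"))) {
  stopifnot(inherits(config, "sim_config"))
  animals <- list()
  trial_chunks <- list()
  counter <- 0L
  for (g in seq_along(presets)) {
    preset <- presets[[g]]
    for (i in seq_len(config$n_per_group)) {
      counter <- counter + 1L
      aid <- sprintf("%s%02d", preset$name, i)
      aseed <- child_seed(config$seed, counter)
      cov <- with_seed(aseed, list(
        weight = max(10, rnorm(1, preset$params$weight_mu_g,
                               preset$params$weight_sd_g)),
        intake = max(0, rnorm(1, preset$params$intake_mu_ml,
                              preset$params$intake_sd_ml))))
      animals[[counter]] <- tibble::tibble(
        animal_id = aid, genotype = preset$name,
        body_weight_g = cov$weight, free_intake_ml = cov$intake)
      trial_chunks[[counter]] <-
        simulate_animal_battery(preset$params, config, aseed, aid,
                                preset$name)
    }
  }
  cohort_table(dplyr::bind_rows(animals), dplyr::bind_rows(trial_chunks))
}

simulate_animal_battery <- function(params, config, aseed, aid, genotype) {
  chunks <- list()
  add <- function(x) chunks[[length(chunks) + 1L]] <<- x
  tseed <- function(offset) child_seed(aseed, offset)
  tasks <- config$tasks
  if ("pr4" %in% tasks) {
    add(simulate_pr_session(params, schedule_preset("pr4"), tseed(101L),
                            aid, genotype))
  }
  if ("pr4_prefed" %in% tasks) {
    prefed_params <- params
    prefed_params$peak_rate_A <- params$peak_rate_A * 0.55
    prefed_params$collect_latency_mu_s <- params$collect_latency_mu_s * 1.6
    add(simulate_pr_session(prefed_params, schedule_preset("pr4"),
                            tseed(102L), aid, genotype,
                            session_index = 2L, prefed = TRUE))
  }
  if ("pr8" %in% tasks) {
    add(simulate_pr_session(params, schedule_preset("pr8"), tseed(103L),
                            aid, genotype, session_index = 3L))
  }
  if ("pr12" %in% tasks) {
    add(simulate_pr_session(params, schedule_preset("pr12"), tseed(104L),
                            aid, genotype, session_index = 4L))
  }
  if ("fr1_uncapped" %in% tasks) {
    add(simulate_fr_session(params, schedule_preset("fr1_uncapped"),
                            tseed(105L), aid, genotype))
  }
  if ("ext" %in% tasks) {
    add(simulate_extinction_series(params, schedule_preset("ext"),
                                   config$ext_sessions_max, tseed(106L),
                                   aid, genotype))
  }
  if ("reinstate" %in% tasks) {
    add(simulate_fr_session(params, schedule_preset("reinstate"),
                            tseed(107L), aid, genotype))
  }
  if ("vd_rev" %in% tasks) {
    add(simulate_vdr_series(params, schedule_preset("vd"),
                            schedule_preset("rev"), tseed(108L),
                            acq_sessions_max = config$acq_sessions_max,
                            rev_sessions_max = config$rev_sessions_max,
                            animal_id = aid, genotype = genotype))
  }
  if (length(chunks) == 0L) return(empty_trial_log())
  dplyr::bind_rows(chunks)
}
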