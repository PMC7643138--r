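test_that("simulated sessions are bit-identical for identical seeds", {
  p <- agent_params()
  pr4 <- schedule_preset("pr4")
  expect_identical(simulate_pr_session(p, pr4, seed = 9),
                   simulate_pr_session(p, pr4, seed = 9))
  expect_identical(
    simulate_extinction_series(p, schedule_preset("ext"), 5, seed = 9),
    simulate_extinction_series(p, schedule_preset("ext"), 5, seed = 9))
  expect_identical(
    simulate_vdr_series(p, schedule_preset("vd"), schedule_preset("rev"),
                        seed = 9),
    simulate_vdr_series(p, schedule_preset("vd"), schedule_preset("rev"),
                        seed = 9))
  cfg <- sim_config(seed = 4, n_per_group = 2, tasks = "pr4")
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_pr_session(agent_params(), schedule_preset("pr4"), 1))
  expect_identical(.Random.seed, before)
})

test_that("noiseless PR sessions match a closed-form schedule oracle", {
  p <- agent_params(peak_rate_A = 600, decay_B = 0, persev_rho = 0,
                    init_deficit_eps = 0, noise_sigma = 0)
  spec <- schedule_preset("pr4")
  s <- simulate_pr_session(p, spec, seed = 1)
  # independent arithmetic: trial k takes req_k / A minutes, plus the
  # collection latency and ITI, until the session cap binds
  t <- 0; k <- 0
  repeat {
    req <- 1 + 4 * k
    trt <- req * 60 / 600
    if (t + trt > spec$session_cap_s) break
    t <- t + trt + p$collect_latency_mu_s + spec$iti_s
    k <- k + 1
    if (t >= spec$session_cap_s) break
  }
  expect_equal(sum(s$n_target_touches == s$requirement), k)
  expect_identical(s, simulate_pr_session(p, spec, seed = 99))  # fully deterministic
})

test_that("a vanishing peak rate yields no completed trials and a timeout", {
  p <- agent_params(peak_rate_A = 1e-9, noise_sigma = 0)
  s <- simulate_pr_session(p, schedule_preset("pr4"), seed = 1)
  expect_equal(sum(s$n_target_touches == s$requirement), 0)
  expect_identical(breakpoint(s), 0L)
  expect_equal(s$session_duration_s[1],
               schedule_preset("pr4")$inactivity_timeout_s)
})

test_that("FR caps and reinstatement reward limits are honoured", {
  p <- agent_params(peak_rate_A = 200, decay_B = 0.01)
  fr1 <- simulate_fr_session(p, schedule_preset("fr1"), seed = 2)
  expect_lte(nrow(fr1), 30)
  expect_equal(nrow(fr1), 30)  # high rate: the trial cap binds

  ri <- simulate_fr_session(p, schedule_preset("reinstate"), seed = 2)
  rewarded <- !is.na(ri$reward_collect_latency_s)
  done <- ri$n_target_touches == ri$requirement
  expect_identical(which(rewarded), which(done)[1:3])

  uc <- simulate_fr_session(agent_params(), schedule_preset("fr1_uncapped"),
                            seed = 3)
  expect_true(nrow(uc) > 5)
  expect_lte(uc$session_duration_s[1], 3600)
})

test_that("rate series from a noiseless agent is exactly exponential and recoverable", {
  p <- agent_params(peak_rate_A = 110, decay_B = 0.3, persev_rho = 0,
                    init_deficit_eps = 0, noise_sigma = 0)
  s <- simulate_pr_session(p, schedule_preset("pr4"), seed = 1)
  pts <- session_rate_series(s)
  expect_gte(nrow(pts), 5)
  expect_equal(pts$y, 110 * exp(-0.3 * pts$x), tolerance = 1e-10)
  f <- fit_decay(pts)
  expect_true(f$reliable)
  expect_lt(abs(f$a - 110) / 110, 1e-6)
  expect_lt(abs(f$b - 0.3) / 0.3, 1e-6)
})

test_that("initiation deficit inflates early-session omissions but not later phases", {
  ext <- schedule_preset("ext")
  # with eps = 0 the three phases have equal response probability
  p0 <- agent_params(init_deficit_eps = 0, learn_alpha = 1e-6)
  phases <- matrix(0, 400, 3)
  for (i in seq_len(400)) {
    s <- simulate_extinction_series(p0, ext, 1, seed = i)
    ph <- segment_extinction_phases(s)
    phases[i, ] <- c(ph$early_pct, ph$middle_pct, ph$late_pct)
  }
  mns <- colMeans(phases)
  se <- max(apply(phases, 2, sd)) / sqrt(400)
  expect_lt(max(mns) - min(mns), 4 * se + 1)

  # with eps large the early phase is suppressed
  p1 <- agent_params(init_deficit_eps = 0.8, learn_alpha = 1e-6)
  ph1 <- colMeans(t(sapply(1:200, function(i) {
    s <- simulate_extinction_series(p1, ext, 1, seed = i)
    ph <- segment_extinction_phases(s)
    c(ph$early_pct, ph$middle_pct, ph$late_pct)
  })))
  expect_lt(ph1[1], ph1[2] - 5)
  expect_lt(ph1[1], ph1[3] - 5)
})

test_that("extinction without learning never reaches the omission criterion", {
  p <- agent_params(learn_alpha = 1e-9, omission_base = 0,
                    init_deficit_eps = 0)
  s <- simulate_extinction_series(p, schedule_preset("ext"), 6, seed = 2)
  expect_equal(max(s$session_index), 6)
  om <- omission_response_pct(s)
  crit <- criterion_spec("omission_pct", 77, 2)
  expect_true(is.na(detect_criterion(om$omission_pct, crit)))
})

test_that("a fast learner with no perseveration recovers quickly after reversal", {
  for (s in c(1, 2, 3)) {
    p <- agent_params(persev_rho = 0, learn_alpha = 1, noise_sigma = 0)
    v <- simulate_vdr_series(p, schedule_preset("vd"),
                             schedule_preset("rev"), seed = s)
    rev <- dplyr::filter(v, task == "REV")
    acc <- dplyr::summarise(
      dplyr::group_by(rev, session_index),
      a = 100 * mean(correct[!correction_trial]))$a
    expect_gt(max(acc[1:min(2, length(acc))]), 50)
  }
})

test_that("perseverative errors increase with the perseveration parameter", {
  n_pairs <- 60
  pe <- sapply(seq_len(n_pairs), function(s) {
    lo <- simulate_vdr_series(agent_params(persev_rho = 0.1),
                              schedule_preset("vd"), schedule_preset("rev"),
                              seed = s)
    hi <- simulate_vdr_series(agent_params(persev_rho = 0.6),
                              schedule_preset("vd"), schedule_preset("rev"),
                              seed = s)
    c(count_perseverative_errors(
        dplyr::filter(lo, task == "REV"))$perseverative_errors,
      count_perseverative_errors(
        dplyr::filter(hi, task == "REV"))$perseverative_errors)
  })
  expect_gt(mean(pe[2, ] - pe[1, ]), 0)
  expect_gte(mean(pe[2, ] >= pe[1, ]), 0.85)
})

test_that("initiation deficit lengthens the first acquisition latency", {
  first_lat <- function(eps, seed) {
    p <- agent_params(init_deficit_eps = eps)
    v <- simulate_vdr_series(p, schedule_preset("vd"),
                             schedule_preset("rev"), seed = seed)
    v$response_latency_s[1]
  }
  lats <- sapply(1:60, function(s) c(first_lat(0, s), first_lat(1.5, s)))
  expect_gt(mean(lats[2, ]), mean(lats[1, ]) * 1.5)
})

test_that("breakpoint is stochastically non-decreasing in peak rate and perseveration", {
  bp <- function(p, s) breakpoint(simulate_pr_session(p, schedule_preset("pr4"), s))
  seeds <- 1:25
  a_lo <- sapply(seeds, function(s) bp(agent_params(peak_rate_A = 60), s))
  a_hi <- sapply(seeds, function(s) bp(agent_params(peak_rate_A = 120), s))
  expect_gt(mean(a_hi), mean(a_lo))
  r_lo <- sapply(seeds, function(s) bp(agent_params(persev_rho = 0.05), s))
  r_hi <- sapply(seeds, function(s) bp(agent_params(persev_rho = 0.7), s))
  expect_gt(mean(r_hi), mean(r_lo))
})

test_that("simulated cohorts are structurally valid with correct group sizes", {
  cfg <- sim_config(seed = 3, n_per_group = 3,
                    tasks = c("pr4", "pr4_prefed", "pr8", "pr12",
                              "fr1_uncapped", "ext", "reinstate", "vd_rev"))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$animals), 6)
  expect_equal(sort(unique(co$animals$genotype)), c("MUT", "WT"))
  expect_equal(nrow(validate_cohort(co)), 0)
  expect_setequal(unique(co$trials$task),
                  c("PR", "FR1_UNCAPPED", "EXT", "REINSTATE", "VD", "REV"))
  expect_true(any(co$trials$prefed))
})

test_that("cohort covariates follow the preset distributions", {
  # law of large numbers on the WT free-intake mean
  means <- sapply(1:40, function(s) {
    co <- simulate_cohort(sim_config(seed = s, n_per_group = 16,
                                     tasks = character(0)))
    mean(co$animals$free_intake_ml[co$animals$genotype == "WT"])
  })
  mu <- genotype_preset("WT")$params$intake_mu_ml
  sdv <- genotype_preset("WT")$params$intake_sd_ml
  se <- sdv / sqrt(16 * 40)
  expect_lt(abs(mean(means) - mu), 3 * se)
})
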