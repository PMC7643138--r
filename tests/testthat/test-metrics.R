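test_that("PR endpoint summary aggregates the session", {
  s <- tibble::tibble(
    animal_id = "a", genotype = "WT", task = "PR", session_index = 1L,
    schedule_kind = "PR", schedule_step = 4L, prefed = FALSE,
    trial_index = 1:4, requirement = c(1L, 5L, 9L, 13L),
    n_target_touches = c(1L, 5L, 9L, 13L), n_blank_touches = c(1L, 0L, 2L, 1L),
    response_latency_s = 1, trt_s = c(5, 20, 45, 80),
    reward_collect_latency_s = c(1, 2, 1.5, 1.5), omitted = FALSE,
    correct = NA, correction_trial = NA, beam_breaks = 120L,
    session_duration_s = 1800)
  out <- summarize_pr(s)
  expect_equal(out$breakpoint, 13L)
  expect_equal(out$total_target_touches, 28)  # 1 + 5 + 9 + 13
  expect_equal(out$total_blank_touches, 4)
  expect_equal(out$mean_collect_latency_s, 1.5)
  expect_equal(out$beam_break_rate, 4)  # 120 breaks / 30 min

  empty <- s[0, ]
  out0 <- summarize_pr(empty)
  expect_equal(out0$breakpoint, 0L)
  expect_equal(out0$total_target_touches, 0)
  expect_true(is.na(out0$mean_collect_latency_s))
})

test_that("extinction sessions partition into three 10-trial phases", {
  early_only <- make_ext_session(1, c(rep(TRUE, 10), rep(FALSE, 20)))
  ph <- segment_extinction_phases(early_only)
  expect_equal(c(ph$early_pct, ph$middle_pct, ph$late_pct), c(100, 0, 0))

  silent <- make_ext_session(1, rep(FALSE, 30))
  ph0 <- segment_extinction_phases(silent)
  expect_equal(c(ph0$early_pct, ph0$middle_pct, ph0$late_pct), c(0, 0, 0))

  short <- early_only[1:25, ]
  expect_error(segment_extinction_phases(short), "25")

  # session-denominator variant
  ph30 <- segment_extinction_phases(early_only, denominator = "session")
  expect_equal(ph30$early_pct, 100 * 10 / 30)
})

test_that("phase counts conserve the session response count", {
  set.seed(5)
  for (i in 1:25) {
    resp <- runif(30) < runif(1)
    s <- make_ext_session(1, resp)
    ph <- segment_extinction_phases(s)
    total <- (ph$early_pct + ph$middle_pct + ph$late_pct) / 100 * 10
    expect_equal(total, sum(resp))
    om <- omission_response_pct(s)
    expect_equal(om$response_pct + om$omission_pct, 100)
    expect_equal(om$response_pct, 100 * mean(resp))
  }
})

test_that("response percentage feeds the omission criterion", {
  s <- make_ext_session(1, c(rep(TRUE, 6), rep(FALSE, 24)))
  expect_equal(omission_response_pct(s)$response_pct, 20)
  s0 <- make_ext_session(1, rep(FALSE, 30))
  expect_equal(omission_response_pct(s0)$omission_pct, 100)
})

test_that("perseverative errors are counted before the criterion pair", {
  # accuracies 20, 35, 55, 60 with errors 24, 20, 13, 12 (30 free trials)
  mk <- function(i, acc, n = 30) {
    n_ok <- round(acc / 100 * n)
    make_choice_session(i, c(rep(TRUE, n_ok), rep(FALSE, n - n_ok)))
  }
  sessions <- dplyr::bind_rows(mk(1, 20), mk(2, 33.3), mk(3, 56.7),
                               mk(4, 60))
  out <- count_perseverative_errors(sessions)
  expect_equal(out$sessions_to_criterion, 4)
  expect_true(out$criterion_met)
  expect_equal(out$perseverative_errors, 24 + 20)
  expect_equal(out$errors_to_criterion, 24 + 20 + 13 + 12)
  expect_equal(out$trials_to_criterion, 120)

  quick <- dplyr::bind_rows(mk(1, 56.7), mk(2, 60))
  expect_equal(count_perseverative_errors(quick)$perseverative_errors, 0)

  never <- dplyr::bind_rows(mk(1, 20), mk(2, 30), mk(3, 40))
  outn <- count_perseverative_errors(never)
  expect_false(outn$criterion_met)
  expect_true(is.na(outn$sessions_to_criterion))
  expect_equal(outn$perseverative_errors, 24 + 21 + 18)
})

test_that("perseverative counting matches a brute-force recount on random series", {
  set.seed(13)
  for (i in 1:300) {
    n_sessions <- sample(2:8, 1)
    sess_list <- lapply(seq_len(n_sessions), function(j) {
      correct <- runif(15) < runif(1)
      tibble::tibble(correct = correct, correction_trial = FALSE)
    })
    sessions <- dplyr::bind_rows(lapply(seq_len(n_sessions), function(j)
      make_choice_session(j, sess_list[[j]]$correct)))
    got <- count_perseverative_errors(sessions)$perseverative_errors
    expect_identical(as.integer(got),
                     as.integer(oracle_perseverative(sess_list)))
  }
})

test_that("acquisition counts run through the criterion session and flag non-learners", {
  mk <- function(i, acc) {
    n_ok <- round(acc / 100 * 30)
    make_choice_session(i, c(rep(TRUE, n_ok), rep(FALSE, 30 - n_ok)))
  }
  two <- dplyr::bind_rows(mk(1, 86.7), mk(2, 86.7))
  out <- trials_errors_to_criterion(two)
  expect_equal(out$sessions_to_criterion, 2)
  expect_equal(out$trials_to_criterion, 60)
  expect_false(out$excluded)

  # correction trials tallied separately, accuracy unaffected
  with_corr <- dplyr::bind_rows(
    make_choice_session(1, c(rep(TRUE, 26), FALSE, TRUE, rep(TRUE, 2),
                             rep(TRUE, 2)),
                        c(rep(FALSE, 27), TRUE, rep(FALSE, 4))),
    mk(2, 90))
  outc <- trials_errors_to_criterion(with_corr)
  expect_equal(outc$correction_trials, 1)
  expect_equal(outc$trials_to_criterion, 61)

  capped <- dplyr::bind_rows(lapply(1:20, function(i) mk(i, 60)))
  outx <- trials_errors_to_criterion(capped)
  expect_true(outx$excluded)
  expect_false(outx$criterion_met)
})

test_that("correlation matrices behave like Pearson correlations", {
  set.seed(3)
  u <- rnorm(1000)
  v <- rnorm(1000)
  m <- tibble::tibble(genotype = "WT", m1 = u, m2 = -u, m3 = v)
  out <- correlation_heatmap(m)$WT
  expect_equal(out["m1", "m1"], 1)
  expect_equal(out["m1", "m2"], -1)
  expect_lt(abs(out["m1", "m3"]), 0.1)

  const <- tibble::tibble(genotype = "WT", m1 = rnorm(10), m2 = rep(2, 10))
  outc <- correlation_heatmap(const)$WT
  expect_true(is.na(outc["m1", "m2"]))
  expect_equal(outc["m2", "m2"], 1)

  expect_error(correlation_heatmap(
    tibble::tibble(genotype = "WT", m1 = 1:2, m2 = 2:3)), "3 animals")
})

test_that("cohort-level VDR summary separates acquisition and reversal", {
  cfg <- sim_config(seed = 2, n_per_group = 2, tasks = "vd_rev")
  co <- simulate_cohort(cfg)
  out <- summarize_vdr_cohort(co)
  expect_equal(nrow(out), 4)
  expect_true(all(out$perseverative_errors <= out$rev_errors))
  expect_true(all(out$vd_trials >= 60))
})
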