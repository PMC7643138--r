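write_test_config <- function(path, ...) {
  cfg <- utils::modifyList(
    list(seed = 11, n_per_group = 2, tasks = c("pr4", "ext", "vd_rev")),
    list(...))
  yaml::write_yaml(cfg, path)
  path
}

test_that("simulate command writes validated, reproducible artifacts", {
  d <- withr::local_tempdir()
  cfgp <- write_test_config(file.path(d, "cfg.yaml"))
  out1 <- file.path(d, "run1")
  cmd_simulate(cfgp, out1)
  expect_true(file.exists(file.path(out1, "trials.csv")))
  expect_true(file.exists(file.path(out1, "covariates.csv")))
  expect_true(file.exists(file.path(out1, "sim_run.json")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  co <- read_cohort_csv(file.path(out1, "trials.csv"),
                        file.path(out1, "covariates.csv"))
  expect_equal(nrow(validate_cohort(co)), 0)

  out2 <- file.path(d, "run2")
  cmd_simulate(cfgp, out2)
  b1 <- readBin(file.path(out1, "trials.csv"), "raw",
                file.size(file.path(out1, "trials.csv")))
  b2 <- readBin(file.path(out2, "trials.csv"), "raw",
                file.size(file.path(out2, "trials.csv")))
  expect_identical(b1, b2)

  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(manifest$command, "simulate")
  expect_equal(manifest$seed, 11)
})

test_that("malformed configs fail loudly with the offending key", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "bad1.yaml")
  yaml::write_yaml(list(seed = 1), p1)
  expect_error(read_sim_config(p1), "n_per_group")
  p2 <- file.path(d, "bad2.yaml")
  yaml::write_yaml(list(seed = 1, n_per_group = 2, typo_key = 5), p2)
  expect_error(read_sim_config(p2), "typo_key")
  expect_error(read_sim_config(file.path(d, "absent.yaml")), "not found")
})

test_that("analyze command writes the full report set", {
  d <- withr::local_tempdir()
  cfgp <- write_test_config(file.path(d, "cfg.yaml"), n_per_group = 3)
  sim_dir <- file.path(d, "sim")
  cmd_simulate(cfgp, sim_dir)
  out <- file.path(d, "reports")
  cmd_analyze(file.path(sim_dir, "trials.csv"),
              file.path(sim_dir, "covariates.csv"), out)
  for (f in c("pr_endpoints.csv", "decay_fits.csv",
              "extinction_phases.csv", "reversal_summary.csv",
              "comparisons.csv", "correlations.csv", "manifest.json")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  fits <- readr::read_csv(file.path(out, "decay_fits.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(fits), 6)
  comp <- readr::read_csv(file.path(out, "comparisons.csv"),
                          show_col_types = FALSE)
  expect_true("p_value" %in% names(comp))
})

test_that("analyze keeps running when some animals are unfittable, and rejects empty input", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, n_per_group = 2, tasks = "pr4")
  co <- simulate_cohort(cfg)
  # append an animal whose PR session cannot support the decay fit
  lazy <- simulate_pr_session(agent_params(peak_rate_A = 2, decay_B = 1),
                              schedule_preset("pr4"), seed = 3,
                              animal_id = "ZZ99", genotype = "WT")
  co2 <- cohort_table(
    dplyr::bind_rows(co$animals,
                     tibble::tibble(animal_id = "ZZ99", genotype = "WT",
                                    body_weight_g = 28, free_intake_ml = 1)),
    dplyr::bind_rows(co$trials, lazy))
  tp <- file.path(d, "t.csv"); cp <- file.path(d, "c.csv")
  write_cohort_csv(co2, tp, cp)
  out <- file.path(d, "rep")
  cmd_analyze(tp, cp, out)
  fits <- readr::read_csv(file.path(out, "decay_fits.csv"),
                          show_col_types = FALSE)
  zz <- fits[fits$animal_id == "ZZ99", ]
  expect_false(zz$reliable)
  expect_false(is.na(zz$exclusion_reason))

  empty <- cohort_table(co$animals[0, ], empty_trial_log())
  ep <- file.path(d, "empty.csv")
  write_cohort_csv(empty, ep)
  expect_error(cmd_analyze(ep, NULL, file.path(d, "rep2")), "empty")
})

test_that("the recovery experiment reports errors honestly", {
  tab <- recover_decay_parameters(a_grid = 100, b_grid = 0.3, reps = 3,
                                  seed = 2)
  expect_equal(nrow(tab), 1)
  expect_true(all(is.finite(tab$median_rel_err_a)))

  zero_tol <- recover_decay_parameters(a_grid = 100, b_grid = 0.3,
                                       reps = 10, seed = 2, tolerance = 0)
  expect_false(zero_tol$pass)  # noise guarantees non-zero error

  d <- withr::local_tempdir()
  cmd_recover(file.path(d, "rec"), seed = 3, a_grid = 100, b_grid = 0.3,
              reps = 5)
  expect_true(file.exists(file.path(d, "rec", "recovery.csv")))
  expect_true(file.exists(file.path(d, "rec", "recovery_summary.json")))
})
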