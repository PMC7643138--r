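#' Read a flat key-value simulation config
#'
#' The config is a flat YAML mapping with the keys of [sim_config()]
#' (`seed`, `n_per_group`, `tasks`, `ext_sessions_max`,
#' `acq_sessions_max`, `rev_sessions_max`); unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path YAML file.
#' @param seed_override Optional seed replacing the config's.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed_override = NULL) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("seed", "n_per_group", "tasks", "ext_sessions_max",
             "acq_sessions_max", "rev_sessions_max")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  need <- c("seed", "n_per_group")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("config missing required key(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!is.null(seed_override)) raw$seed <- seed_override
  do.call(sim_config, raw)
}

write_manifest <- function(out_dir, command, config_digest, seed,
                           output_paths) {
  manifest <- list(
    command = command,
    config_digest = config_digest,
    seed = seed,
    output_paths = as.list(basename(output_paths)),
    package_version = as.character(utils::packageVersion("operant")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write its trial-log artifacts
#'
#' Writes `trials.csv`, `covariates.csv`, a JSON sidecar recording the
#' configuration and presets, and a run manifest.
#'
#' @param config_path Path to a YAML config (see [read_sim_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(config_path, out_dir, seed = NULL) {
  config <- read_sim_config(config_path, seed_override = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- list(genotype_preset("WT"), genotype_preset("MUT"))
  cohort <- simulate_cohort(config, presets)
  trials_path <- file.path(out_dir, "trials.csv")
  cov_path <- file.path(out_dir, "covariates.csv")
  write_cohort_csv(cohort, trials_path, cov_path)
  sidecar <- file.path(out_dir, "sim_run.json")
  jsonlite::write_json(
    list(config = unclass(config),
         presets = lapply(presets, function(p)
           c(list(name = p$name), unclass(p$params)))),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 unname(tools::md5sum(config_path)), config$seed,
                 c(trials_path, cov_path, sidecar))
}

#' Analyse a cohort trial log and write report CSVs
#'
#' Runs the full endpoint pipeline on a validated trial log and writes
#' the standard report files: `pr_endpoints.csv`, `decay_fits.csv`,
#' `extinction_phases.csv`, `reversal_summary.csv`, `comparisons.csv` and
#' `correlations.csv`. Every exclusion (unreliable fit, animal that never
#' reached a criterion) is recorded in the reports, never silently
#' dropped; unreliable fits are excluded from the group comparisons.
#'
#' @param trials_path Trial-log CSV.
#' @param covariates_path Covariates CSV (optional).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
cmd_analyze <- function(trials_path, covariates_path = NULL, out_dir) {
  cohort <- read_cohort_csv(trials_path, covariates_path, validate = FALSE)
  v <- validate_cohort(cohort)
  if (nrow(v) > 0) {
    abort(c("cohort failed validation:",
            stats::setNames(head(v$message, 10),
                            rep("x", min(10, nrow(v))))))
  }
  if (nrow(cohort$trials) == 0L) abort("cohort trial log is empty.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  pr <- summarize_pr_cohort(cohort)
  paths["pr_endpoints"] <- file.path(out_dir, "pr_endpoints.csv")
  readr::write_csv(pr, paths[["pr_endpoints"]], na = "")

  steps <- sort(unique(cohort$trials$schedule_step[cohort$trials$task == "PR"]))
  fits <- purrr::map_dfr(steps, function(st)
    fit_cohort_decay(cohort, task = "PR", schedule_step = st))
  paths["decay_fits"] <- file.path(out_dir, "decay_fits.csv")
  readr::write_csv(fits, paths[["decay_fits"]], na = "")

  ext <- dplyr::filter(cohort$trials, .data$task == "EXT")
  phases <- if (nrow(ext) > 0) {
    groups <- dplyr::group_split(
      dplyr::group_by(ext, .data$animal_id, .data$session_index))
    purrr::map_dfr(groups, function(s)
      dplyr::bind_cols(tibble::tibble(animal_id = s$animal_id[1],
                                      genotype = s$genotype[1]),
                       segment_extinction_phases(s)))
  } else tibble::tibble()
  paths["extinction_phases"] <- file.path(out_dir, "extinction_phases.csv")
  readr::write_csv(phases, paths[["extinction_phases"]], na = "")

  vdr <- if (any(cohort$trials$task %in% c("VD", "REV"))) {
    summarize_vdr_cohort(cohort)
  } else tibble::tibble()
  paths["reversal_summary"] <- file.path(out_dir, "reversal_summary.csv")
  readr::write_csv(vdr, paths[["reversal_summary"]], na = "")

  measures <- cohort_measure_table(cohort, pr, fits, phases, vdr)
  comparisons <- if (length(unique(measures$genotype)) == 2 &&
                     nrow(measures) >= 6) {
    compare_groups_table(measures)
  } else tibble::tibble()
  paths["comparisons"] <- file.path(out_dir, "comparisons.csv")
  readr::write_csv(comparisons, paths[["comparisons"]], na = "")

  cors <- correlations_long(measures)
  paths["correlations"] <- file.path(out_dir, "correlations.csv")
  readr::write_csv(cors, paths[["correlations"]], na = "")

  write_manifest(out_dir, "analyze", unname(tools::md5sum(trials_path)),
                 NA_integer_, paths)
}

#' Assemble the per-animal measure table
#'
#' One row per animal: covariates, first-session PR4 breakpoint, reliable
#' decay-fit parameters, mean early-phase extinction response percentage
#' and reversal perseveration counts — the measures entering group
#' comparisons and correlation heatmaps.
#'
#' @param cohort A [cohort_table()].
#' @param pr,fits,phases,vdr Optional precomputed report tables; computed
#'   on demand when `NULL`.
#' @return Tibble of per-animal measures.
#' @export
cohort_measure_table <- function(cohort, pr = NULL, fits = NULL,
                                 phases = NULL, vdr = NULL) {
  pr <- pr %||% summarize_pr_cohort(cohort)
  out <- cohort$animals
  if (nrow(pr) > 0) {
    bp <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(pr, !.data$prefed),
                      .data$animal_id, .data$schedule_step),
      breakpoint = .data$breakpoint[1], .groups = "drop")
    bp <- tidyr::pivot_wider(bp, names_from = "schedule_step",
                             values_from = "breakpoint",
                             names_prefix = "bp")
    out <- dplyr::left_join(out, bp, by = "animal_id")
  }
  if (!is.null(fits) && nrow(fits) > 0) {
    rel <- dplyr::filter(fits, .data$reliable)
    if (nrow(rel) > 0) {
      ab <- tidyr::pivot_wider(
        rel[c("animal_id", "schedule_step", "a", "b")],
        names_from = "schedule_step", values_from = c("a", "b"),
        names_sep = "_pr")
      out <- dplyr::left_join(out, ab, by = "animal_id")
    }
  }
  if (!is.null(phases) && nrow(phases) > 0) {
    early <- dplyr::summarise(dplyr::group_by(phases, .data$animal_id),
                              ext_early_pct = mean(.data$early_pct),
                              .groups = "drop")
    out <- dplyr::left_join(out, early, by = "animal_id")
  }
  if (!is.null(vdr) && nrow(vdr) > 0) {
    out <- dplyr::left_join(
      out, vdr[c("animal_id", "vd_trials", "vd_errors",
                 "vd_correction_trials", "rev_trials",
                 "perseverative_errors")],
      by = "animal_id")
  }
  out
}

correlations_long <- function(measures) {
  groups <- unique(measures$genotype)
  enough <- vapply(groups, function(g)
    sum(measures$genotype == g) >= 3, logical(1))
  if (!any(enough)) return(tibble::tibble())
  mats <- correlation_heatmap(measures[measures$genotype %in%
                                         groups[enough], , drop = FALSE])
  purrr::map_dfr(names(mats), function(g) {
    m <- mats[[g]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tibble::tibble(genotype = g,
                   measure1 = rownames(m)[idx[, 1]],
                   measure2 = colnames(m)[idx[, 2]],
                   pearson_r = m[idx])
  })
}

#' Parameter-recovery experiment
#'
#' Simulates rate series from a grid of true (a, b) values with
#' multiplicative lognormal noise, refits each with [fit_decay()], and
#' reports the median estimates, bias and relative error per grid cell
#' together with a pass/fail flag against a tolerance on the median
#' relative error.
#'
#' @param a_grid,b_grid True parameter grids (defaults 50/100/150 and
#'   0.1/0.3/0.6).
#' @param sigma Lognormal noise sd (default 0.15).
#' @param n_points Points per series (default 13, a typical number of
#'   completed PR4 trials).
#' @param reps Replicates per cell (default 200).
#' @param seed Master seed.
#' @param tolerance Pass threshold on the relative error of the median
#'   estimate (default 0.05).
#' @return Tibble with one row per (a, b) cell: the median estimates, the
#'   relative error of each median against truth (`median_rel_err_*`, a
#'   median-bias measure), the median per-replicate absolute relative
#'   error (`spread_*`, a sampling-variability measure), and `pass`.
#' @export
recover_decay_parameters <- function(a_grid = c(50, 100, 150),
                                     b_grid = c(0.1, 0.3, 0.6),
                                     sigma = 0.15, n_points = 13L,
                                     reps = 200L, seed = 1L,
                                     tolerance = 0.05) {
  grid <- expand.grid(a = a_grid, b = b_grid)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    a <- grid$a[i]; b <- grid$b[i]
    ests <- with_seed(child_seed(seed, i), {
      vapply(seq_len(reps), function(r) {
        x <- seq_len(n_points)
        y <- a * exp(-b * x) * exp(rnorm(n_points, 0, sigma))
        f <- fit_decay(tibble::tibble(x = x, y = y))
        c(f$a, f$b)
      }, numeric(2))
    })
    med_a <- median(ests[1, ])
    med_b <- median(ests[2, ])
    rel_a <- abs(med_a - a) / a
    rel_b <- abs(med_b - b) / b
    tibble::tibble(true_a = a, true_b = b, median_a_hat = med_a,
                   median_b_hat = med_b, median_rel_err_a = rel_a,
                   median_rel_err_b = rel_b,
                   spread_a = median(abs(ests[1, ] - a) / a),
                   spread_b = median(abs(ests[2, ] - b) / b),
                   pass = rel_a < tolerance & rel_b < tolerance)
  })
}

#' Run the parameter-recovery experiment and write its report
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Passed to [recover_decay_parameters()].
#' @return Invisibly, the manifest list.
#' @export
cmd_recover <- function(out_dir, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- recover_decay_parameters(seed = seed, ...)
  path <- file.path(out_dir, "recovery.csv")
  readr::write_csv(tab, path, na = "")
  summary_path <- file.path(out_dir, "recovery_summary.json")
  jsonlite::write_json(
    list(n_cells = nrow(tab), n_pass = sum(tab$pass),
         all_pass = all(tab$pass)),
    summary_path, auto_unbox = TRUE)
  write_manifest(out_dir, "recover", NA_character_, seed,
                 c(path, summary_path))
}
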