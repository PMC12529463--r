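#' Pipeline configuration
#'
#' Single structured configuration driving the end-to-end pipeline. Every
#' default matches the task's printed value where one exists (arena side,
#' target coordinates, kinematic speeds, TR, run duration, high-pass
#' cutoff, number of aCompCor components, feedback bands, cohort sizes);
#' remaining values are the package's calibrated simulation defaults.
#'
#' @param arena_side Arena side length in vm.
#' @param targets Target registry data frame.
#' @param group_params Per-group [agent_params()] list.
#' @param n_young,n_old Cohort sizes.
#' @param trials_per_participant Named (young/old) per-run trial counts.
#' @param scan A [scan_config()].
#' @param rois Named list of per-ROI, per-group generating modulator means.
#' @param beta_between_sd Between-participant SD of the generating
#'   modulator effect.
#' @param bias_coupling Generating slope of modulator effect on boundary
#'   bias in older adults (signal units per vm per unit bias).
#' @param truth Baseline [bold_truth()] (noise, motion, physiological and
#'   drift settings shared by every run).
#' @param feedback_green_max,feedback_yellow_max Feedback band edges (vm).
#' @param occupancy_thresholds Boundary-occupancy thresholds (fractions of
#'   the side).
#' @param clamp_floor Wall-distance denominator floor (vm).
#' @param rng_seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(arena_side = 160,
                       targets = default_targets(),
                       group_params = default_group_params(),
                       n_young = 20, n_old = 21,
                       trials_per_participant = c(young = 48, old = 37),
                       scan = scan_config(),
                       rois = list(ec = c(young = -0.0001, old = -0.004),
                                   subiculum = c(young = -0.001, old = -0.003)),
                       beta_between_sd = 0.003,
                       bias_coupling = -0.016,
                       truth = bold_truth(),
                       feedback_green_max = 20,
                       feedback_yellow_max = 30,
                       occupancy_thresholds = c(0.05, 0.10, 0.15),
                       clamp_floor = 0.1,
                       rng_seed = 1L) {
  cfg <- list(arena_side = arena_side, targets = targets,
              group_params = group_params, n_young = n_young, n_old = n_old,
              trials_per_participant = trials_per_participant, scan = scan,
              rois = rois, beta_between_sd = beta_between_sd,
              bias_coupling = bias_coupling, truth = truth,
              feedback_green_max = feedback_green_max,
              feedback_yellow_max = feedback_yellow_max,
              occupancy_thresholds = occupancy_thresholds,
              clamp_floor = clamp_floor, rng_seed = as.integer(rng_seed))
  stopifnot(arena_side > 0, n_young >= 0, n_old >= 0,
            all(c("young", "old") %in% names(group_params)),
            feedback_green_max < feedback_yellow_max,
            all(occupancy_thresholds > 0 & occupancy_thresholds < 0.5))
  class(cfg) <- "run_config"
  cfg
}

# Concatenate a participant's trial trajectories into one continuous
# session on the scan's time axis, with a 2-s stationary gap between
# trials, looping over the trials until the run duration is covered.
session_from_trials <- function(trajectories, participant_id, scan,
                                sampling_rate = 10) {
  sub <- trajectories[trajectories$participant_id == participant_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no trajectories for participant", call. = FALSE)
  dt <- 1 / sampling_rate
  gap <- round(2 / dt)
  pieces <- split(sub, sub$trial_index)
  out <- list()
  t0 <- 0
  repeat {
    for (p in pieces) {
      tt <- p$t - p$t[1]
      out[[length(out) + 1L]] <- data.frame(
        t = t0 + tt, x = p$x, y = p$y, heading = p$heading,
        moving = p$moving, stringsAsFactors = FALSE)
      t0 <- t0 + max(tt) + dt
      last <- p[nrow(p), ]
      out[[length(out) + 1L]] <- data.frame(
        t = t0 + dt * (seq_len(gap) - 1), x = last$x, y = last$y,
        heading = last$heading, moving = "stationary", stringsAsFactors = FALSE)
      t0 <- t0 + gap * dt
      if (t0 >= scan$run_duration) break
    }
    if (t0 >= scan$run_duration) break
  }
  traj <- do.call(rbind, out)
  traj <- traj[traj$t <= scan$run_duration, , drop = FALSE]
  rownames(traj) <- NULL
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Run the full simulation-to-inference pipeline
#'
#' Simulates a two-group cohort, scores and filters its behavior, fits the
#' trial-level mixed models, simulates one BOLD run per participant and ROI
#' with a known modulator effect coupled to that participant's boundary
#' bias, estimates the first-level GLMs, and runs the group-level battery
#' (one-sample and Bayesian t-tests per group and ROI, group and
#' brain-behavior regressions, Levene variance test on BPI, and the
#' median-split comparison among older adults). Optionally writes all
#' result tables, a text report and a provenance block (config hash, seed,
#' package version) to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param verbose Log stage-level progress.
#' @return A list of class `pipeline_result` with elements `cohort`,
#'   `scored`, `summary`, `mixed_models`, `bpi_error_correlation`,
#'   `participants` (per-participant table incl. betas and truths),
#'   `group_tests`, `group_regression`, `brain_behavior`, `levene_bpi`,
#'   `median_split`, `provenance`.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = NULL,
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ar <- arena(config$arena_side)
  stage <- "simulate-behavior"
  result <- tryCatch({
    say("[%s] cohort: %d young + %d old", stage, config$n_young, config$n_old)
    cohort <- simulate_cohort(config$n_young, config$n_old,
                              config$group_params,
                              config$trials_per_participant,
                              ar, config$targets, config$rng_seed)

    stage <- "score-behavior"
    scored <- score_trials(cohort, ar,
                           occupancy_thresholds = config$occupancy_thresholds)
    n_out <- sum(scored$outlier)
    say("[%s] %d trials scored, %d outliers removed (%.2f%%)", stage,
        nrow(scored), n_out, 100 * n_out / nrow(scored))
    summ <- participant_summary(scored)
    overall <- summ[summ$target == "all", , drop = FALSE]

    stage <- "behavior-stats"
    kept <- scored[!scored$outlier, , drop = FALSE]
    mixed <- list(
      error = mixed_model_fit(kept, "error"),
      bias_two_wall = mixed_model_fit(kept, "bias_two_wall"),
      bpi_median = mixed_model_fit(kept, "bpi_median")
    )
    bpi_err <- metric_correlation(
      participant_target_table(summ), "bpi_median_mean", "error_mean",
      grouping = c("age_group", "target"))

    stage <- "simulate-bold"
    participants <- build_participant_table(overall, config)
    betas <- fit_all_runs(cohort, participants, config, ar, say)
    participants <- cbind(participants, betas)

    stage <- "group-stats"
    group_tests <- roi_group_tests(participants, names(config$rois))
    group_reg <- lapply(stats::setNames(nm = names(config$rois)), function(r) {
      tab <- participants
      tab$age_old <- ifelse(tab$age_group == "old", 0.5, -0.5)
      covariate_regression(tab, paste0("beta_", r),
                           c("age_old", paste0("lin_disp_", r),
                             paste0("ang_disp_", r), paste0("tsnr_", r)))
    })
    old_tab <- participants[participants$age_group == "old", , drop = FALSE]
    brain_behavior <- lapply(stats::setNames(nm = names(config$rois)), function(r) {
      covariate_regression(old_tab, paste0("beta_", r),
                           c("bias_two_wall_mean", "bpi_median_mean", "age", "moca"))
    })
    levene_bpi <- variance_equality_test(participants$bpi_median_mean,
                                         participants$age_group)
    ms_outcomes <- c("bias_two_wall_mean", "bpi_median_mean",
                     paste0("beta_", names(config$rois)))
    med_split <- median_split_compare(old_tab, "error_mean", ms_outcomes)

    prov <- list(config_hash = config_hash(deparse(config[setdiff(names(config), "targets")])),
                 rng_seed = config$rng_seed,
                 package_version = as.character(utils::packageVersion("boundnav")),
                 timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

    list(cohort = cohort, scored = scored, summary = summ,
         mixed_models = mixed, bpi_error_correlation = bpi_err,
         participants = participants, group_tests = group_tests,
         group_regression = group_reg, brain_behavior = brain_behavior,
         levene_bpi = levene_bpi, median_split = med_split,
         provenance = prov)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, config)
  result
}

# Per-participant x target table in wide-enough form for correlations.
participant_target_table <- function(summ) {
  summ[summ$target != "all", , drop = FALSE]
}

# Participant-level covariates: per-participant behavioral aggregates plus
# simulated demographic covariates (age, cognitive screening score).
build_participant_table <- function(overall, config) {
  tab <- overall[, c("participant_id", "age_group", "n_trials",
                     "error_mean", "error_median", "bias_two_wall_mean",
                     "bias_nearest_wall_mean", "bpi_median_mean",
                     "bpi_mean_mean")]
  local_seed(derive_seed(config$rng_seed, 0L, 2L), {
    young <- tab$age_group == "young"
    tab$age <- ifelse(young, stats::rnorm(nrow(tab), 24.5, 3.3),
                      stats::rnorm(nrow(tab), 69.3, 4.8))
    tab$moca <- round(pmin(pmax(ifelse(young, stats::rnorm(nrow(tab), 28, 1.2),
                                       stats::rnorm(nrow(tab), 26.5, 1.8)),
                                24), 30))
  })
  rownames(tab) <- NULL
  tab
}

# Simulate and fit one BOLD run per participant and ROI; the generating
# modulator effect couples to the participant's boundary bias (older
# adults) around the group mean.
fit_all_runs <- function(cohort, participants, config, ar, say) {
  rois <- names(config$rois)
  n <- nrow(participants)
  out <- data.frame(row.names = seq_len(n))
  truth_base <- config$truth
  fs <- config$group_params$young$sampling_rate
  sessions <- lapply(participants$participant_id, function(pid) {
    session_from_trials(cohort$trajectories, pid, config$scan, fs)
  })
  for (r in rois) {
    say("[simulate-bold] ROI %s: %d runs", r, n)
    beta_true <- beta_hat <- tsnr <- lin <- ang <- numeric(n)
    for (i in seq_len(n)) {
      grp <- participants$age_group[i]
      seed_i <- derive_seed(config$rng_seed, i, 3L + match(r, rois))
      bias_dev <- participants$bias_two_wall_mean[i] -
        mean(participants$bias_two_wall_mean[participants$age_group == grp])
      coup <- if (grp == "old") config$bias_coupling else 0
      beta_true[i] <- local_seed(seed_i, {
        config$rois[[r]][[grp]] + coup * bias_dev +
          stats::rnorm(1, 0, config$beta_between_sd)
      })
      truth_i <- truth_base
      truth_i$beta_pmod <- beta_true[i]
      run <- simulate_bold_run(sessions[[i]], config$scan, truth_i,
                               rng_seed = derive_seed(seed_i, 1L), ar)
      fit <- fit_bold_run(run)
      qm <- quality_metrics(run$roi, run$motion)
      beta_hat[i] <- fit$beta_pmod
      tsnr[i] <- qm$tsnr
      lin[i] <- qm$mean_linear_displacement
      ang[i] <- qm$mean_angular_displacement
    }
    out[[paste0("beta_true_", r)]] <- beta_true
    out[[paste0("beta_", r)]] <- beta_hat
    out[[paste0("tsnr_", r)]] <- tsnr
    out[[paste0("lin_disp_", r)]] <- lin
    out[[paste0("ang_disp_", r)]] <- ang
  }
  out
}

# One-sample frequentist and Bayesian tests per group x ROI.
roi_group_tests <- function(participants, rois) {
  rows <- list()
  for (r in rois) {
    for (g in c("young", "old")) {
      v <- participants[[paste0("beta_", r)]][participants$age_group == g]
      tt <- suppressWarnings(one_sample_test(v))
      bf <- bayes_factor_one_sample(v)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, age_group = g, n = tt$n, mean = tt$mean, t = tt$t,
        df = tt$df, p = tt$p, shapiro_p = tt$shapiro_p, bf01 = bf$bf01,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  participants: %d | trials scored: %d\n",
              nrow(x$participants), nrow(x$scored)))
  cat(sprintf("  config hash %s, seed %d\n",
              x$provenance$config_hash, x$provenance$rng_seed))
  invisible(x)
}

# ---- output writing ---------------------------------------------------

write_stamped_csv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# boundnav %s | config %s | seed %d",
                     prov$package_version, prov$config_hash, prov$rng_seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

write_pipeline_outputs <- function(result, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- result$provenance
  write_stamped_csv(result$scored, file.path(out_dir, "trial_metrics.csv"), prov)
  write_stamped_csv(result$summary, file.path(out_dir, "participant_summary.csv"), prov)
  write_stamped_csv(result$participants, file.path(out_dir, "participants.csv"), prov)
  write_stamped_csv(result$group_tests, file.path(out_dir, "group_tests.csv"), prov)
  write_stamped_csv(result$median_split$comparison,
                    file.path(out_dir, "median_split.csv"), prov)
  writeLines(render_report(result), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render the pipeline's text report
#'
#' Human-readable summary mirroring the analysis structure: behavioral
#' precision and target effects, boundary bias, navigation (BPI and its
#' variance), boundary-distance BOLD modulation per group and ROI,
#' brain-behavior links, and the median-split comparison.
#'
#' @param result A `pipeline_result`.
#' @return Character vector of report lines.
#' @export
render_report <- function(result) {
  p <- result$participants
  fmt_fx <- function(fx) {
    apply(fx$fixed_effects, 1, function(r) {
      sprintf("    %-28s b = %8.4g  SE = %7.3g  t = %6.2f  p = %.4g",
              r[["term"]], as.numeric(r[["estimate"]]), as.numeric(r[["se"]]),
              as.numeric(r[["t"]]), as.numeric(r[["p"]]))
    })
  }
  lines <- c(
    "boundnav pipeline report",
    sprintf("config %s | seed %d | package %s",
            result$provenance$config_hash, result$provenance$rng_seed,
            result$provenance$package_version),
    "",
    "== Behavior: spatial memory precision (Euclidean error) ==",
    sprintf("  group mean error: young %.2f vm, old %.2f vm",
            mean(p$error_mean[p$age_group == "young"]),
            mean(p$error_mean[p$age_group == "old"])),
    "  mixed model (error ~ age_group * target):",
    fmt_fx(result$mixed_models$error),
    "",
    "== Behavior: boundary bias ==",
    sprintf("  group mean bias (two-wall): young %.3f, old %.3f",
            mean(p$bias_two_wall_mean[p$age_group == "young"]),
            mean(p$bias_two_wall_mean[p$age_group == "old"])),
    "  mixed model (bias ~ age_group * target):",
    fmt_fx(result$mixed_models$bias_two_wall),
    "",
    "== Navigation: boundary proximity index ==",
    sprintf("  group mean BPI (median-based): young %.4f (SD %.4f), old %.4f (SD %.4f)",
            mean(p$bpi_median_mean[p$age_group == "young"]),
            stats::sd(p$bpi_median_mean[p$age_group == "young"]),
            mean(p$bpi_median_mean[p$age_group == "old"]),
            stats::sd(p$bpi_median_mean[p$age_group == "old"])),
    sprintf("  Levene variance test: F(%d, %d) = %.2f, p = %.4g",
            result$levene_bpi$df1, result$levene_bpi$df2,
            result$levene_bpi$F, result$levene_bpi$p),
    "  mixed model (BPI ~ age_group * target):",
    fmt_fx(result$mixed_models$bpi_median),
    "",
    "== BOLD: boundary-distance modulation (pmod betas) ==",
    apply(result$group_tests, 1, function(r) {
      sprintf("  %-10s %-6s M = %9.5g  t(%s) = %6.2f  p = %.4g  BF01 = %.2f",
              r[["roi"]], r[["age_group"]], as.numeric(r[["mean"]]),
              r[["df"]], as.numeric(r[["t"]]), as.numeric(r[["p"]]),
              as.numeric(r[["bf01"]]))
    }),
    "",
    "== Brain-behavior (older adults): beta_pmod ~ bias + BPI + age + MoCA ==",
    unlist(lapply(names(result$brain_behavior), function(r) {
      c(sprintf("  ROI %s:", r),
        apply(result$brain_behavior[[r]], 1, function(x) {
          sprintf("    %-22s b = %9.4g  SE = %8.3g  p = %.4g",
                  x[["term"]], as.numeric(x[["estimate"]]),
                  as.numeric(x[["se"]]), as.numeric(x[["p"]]))
        }))
    })),
    "",
    "== Median split of older adults by mean Euclidean error ==",
    apply(result$median_split$comparison, 1, function(r) {
      sprintf("  %-22s low = %9.4g  high = %9.4g  t(%s) = %6.2f  p = %.4g",
              r[["outcome"]], as.numeric(r[["mean_low_performing"]]),
              as.numeric(r[["mean_high_performing"]]), r[["df"]],
              as.numeric(r[["t"]]), as.numeric(r[["p"]]))
    })
  )
  unlist(lines)
}

#' Print the default target boundary-distance sums
#'
#' Convenience check of the target registry: the summed distance to the
#' two closest walls for each default target (49, 96 and 102 vm).
#'
#' @param targets Target registry data frame.
#' @param arena An [arena()].
#' @return Named numeric vector of two-wall distance sums, invisibly;
#'   prints one line per target.
#' @export
targets_check <- function(targets = default_targets(), arena = boundnav::arena()) {
  d <- two_wall_distance_sum(cbind(targets$x, targets$y), arena)
  names(d) <- targets$name
  for (i in seq_along(d)) {
    cat(sprintf("%-10s (%3g, %3g): two-wall distance sum %g vm\n",
                targets$name[i], targets$x[i], targets$y[i], d[i]))
  }
  invisible(d)
}

# ---- input validation -------------------------------------------------

#' Validate input tables against the pipeline schema
#'
#' Schema and content checks for externally supplied tables: trajectory
#' tables (TSV: participant_id, trial_index, t, x, y, heading, moving),
#' trial tables (CSV: participant_id, age_group, trial_index, target,
#' target_x/y, start_x/y, response_x/y), ROI series and motion-parameter
#' tables (TSV). Positions must lie inside the arena and trajectory time
#' must increase within each trial; failures name the offending file, row
#' or column.
#'
#' @param paths Named list with any of `trajectories`, `trials`, `roi`,
#'   `motion` file paths.
#' @param arena An [arena()].
#' @return Data frame with columns `file`, `check`, `pass`, `message`.
#' @export
validate_inputs <- function(paths, arena = boundnav::arena()) {
  out <- list()
  add <- function(file, check, pass, message = "") {
    out[[length(out) + 1L]] <<- data.frame(file = file, check = check,
                                           pass = pass, message = message,
                                           stringsAsFactors = FALSE)
  }
  check_positions <- function(df, file, xcol, ycol) {
    L <- arena$side_length
    bad <- which(!is.finite(df[[xcol]]) | df[[xcol]] < 0 | df[[xcol]] > L |
                   !is.finite(df[[ycol]]) | df[[ycol]] < 0 | df[[ycol]] > L)
    if (length(bad)) {
      add(file, "positions-in-arena", FALSE,
          sprintf("row %d: (%s, %s) outside [0, %g]", bad[1],
                  xcol, ycol, L))
    } else add(file, "positions-in-arena", TRUE)
  }
  read_any <- function(path, sep) {
    tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                               comment.char = "#", stringsAsFactors = FALSE),
             error = function(e) e)
  }
  if (!is.null(paths$trajectories)) {
    f <- paths$trajectories
    df <- read_any(f, "\t")
    if (inherits(df, "error")) {
      add(f, "readable", FALSE, conditionMessage(df))
    } else {
      add(f, "readable", TRUE)
      need <- c("participant_id", "trial_index", "t", "x", "y", "heading", "moving")
      missing <- setdiff(need, names(df))
      if (length(missing)) {
        add(f, "columns", FALSE, paste("missing column(s):",
                                       paste(missing, collapse = ", ")))
      } else {
        add(f, "columns", TRUE)
        check_positions(df, f, "x", "y")
        bad_mv <- which(!df$moving %in% c("stationary", "rotation", "translation"))
        if (length(bad_mv)) {
          add(f, "moving-flag", FALSE,
              sprintf("row %d: unknown moving flag '%s'", bad_mv[1],
                      df$moving[bad_mv[1]]))
        } else add(f, "moving-flag", TRUE)
        mono <- all(unlist(tapply(df$t, paste(df$participant_id, df$trial_index),
                                  function(tt) all(diff(tt) > 0))))
        add(f, "time-increasing", mono,
            if (!mono) "time not strictly increasing within a trial" else "")
      }
    }
  }
  if (!is.null(paths$trials)) {
    f <- paths$trials
    df <- read_any(f, ",")
    if (inherits(df, "error")) {
      add(f, "readable", FALSE, conditionMessage(df))
    } else {
      add(f, "readable", TRUE)
      need <- c("participant_id", "age_group", "trial_index", "target",
                "target_x", "target_y", "start_x", "start_y",
                "response_x", "response_y")
      missing <- setdiff(need, names(df))
      if (length(missing)) {
        add(f, "columns", FALSE, paste("missing column(s):",
                                       paste(missing, collapse = ", ")))
      } else {
        add(f, "columns", TRUE)
        check_positions(df, f, "target_x", "target_y")
        check_positions(df, f, "response_x", "response_y")
        bad_grp <- which(!df$age_group %in% c("young", "old"))
        if (length(bad_grp)) {
          add(f, "age-group", FALSE, sprintf("row %d: unknown age group '%s'",
                                             bad_grp[1], df$age_group[bad_grp[1]]))
        } else add(f, "age-group", TRUE)
      }
    }
  }
  for (nm in c("roi", "motion")) {
    if (is.null(paths[[nm]])) next
    f <- paths[[nm]]
    df <- read_any(f, "\t")
    if (inherits(df, "error")) {
      add(f, "readable", FALSE, conditionMessage(df))
      next
    }
    add(f, "readable", TRUE)
    num_ok <- all(vapply(df, is.numeric, logical(1)))
    add(f, "numeric", num_ok, if (!num_ok) "non-numeric column present" else "")
    if (nm == "motion" && ncol(df) < 6) {
      add(f, "columns", FALSE, "motion table needs 6 parameter columns")
    } else if (nm == "motion") add(f, "columns", TRUE)
  }
  do.call(rbind, out)
}

#' Write a cohort's tables to disk
#'
#' Trajectories as TSV, trials as CSV, drawn per-participant parameters
#' (the generator's ground truth) as a sidecar TSV.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_traj <- file.path(dir, "trajectories.tsv")
  p_tr <- file.path(dir, "trials.csv")
  p_truth <- file.path(dir, "cohort_truth.tsv")
  utils::write.table(cohort$trajectories, p_traj, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$trials, p_tr, row.names = FALSE)
  utils::write.table(cohort$params, p_truth, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(p_traj, p_tr, p_truth))
}
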