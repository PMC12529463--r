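# Draw an individual's parameter set around the group values (truncated to
# the legal range), modelling between-participant differences in boundary
# reliance.
individual_params <- function(group) {
  lam <- min(max(stats::rnorm(1, group$lambda, group$lambda_sd), 0), 1)
  att <- min(max(stats::rnorm(1, group$boundary_attraction, group$attraction_sd), 0), 1)
  p <- group
  p$lambda <- lam
  p$boundary_attraction <- att
  p
}

#' Simulate a two-group cohort of navigation trials
#'
#' Generates a reproducible table of object-location memory trials for a
#' young and an old group. Each trial starts at a random location in the
#' arena; the agent produces a remembered-location response for one of the
#' three targets (cycled in random order) via [simulate_response()], then
#' navigates from the start to that response via [simulate_trajectory()].
#' Per-participant parameter values are drawn around the group values
#' (`lambda_sd`, `attraction_sd`), and per-participant sub-seeds are derived
#' deterministically from the master seed, so cohorts are reproducible and
#' extensible.
#'
#' @param n_young,n_old Number of participants per group.
#' @param group_params Named list with [agent_params()] elements `young`
#'   and `old`; defaults to [default_group_params()].
#' @param trials_per_participant Trials per participant; either a single
#'   count or a named vector/list with elements `young` and `old`. The
#'   defaults (48 young, 37 old) mirror the per-run trial counts of the
#'   task, where scan duration was matched across groups.
#' @param arena An [arena()].
#' @param targets Target registry (data frame with `name`, `x`, `y`);
#'   defaults to [default_targets()].
#' @param rng_seed Master integer seed.
#' @return A list of class `cohort` with elements:
#'   \describe{
#'     \item{trials}{data frame: `participant_id`, `age_group`,
#'       `trial_index`, `target`, `target_x`, `target_y`, `start_x`,
#'       `start_y`, `response_x`, `response_y`, `response_time`, `clipped`.}
#'     \item{trajectories}{data frame: `participant_id`, `trial_index`,
#'       `t`, `x`, `y`, `heading`, `moving`.}
#'     \item{params}{per-participant drawn parameter values.}
#'   }
#' @export
simulate_cohort <- function(n_young, n_old,
                            group_params = default_group_params(),
                            trials_per_participant = c(young = 48, old = 37),
                            arena = boundnav::arena(),
                            targets = default_targets(),
                            rng_seed = 1L) {
  stopifnot(n_young >= 0, n_old >= 0, n_young + n_old > 0)
  stopifnot(all(c("young", "old") %in% names(group_params)))
  if (length(trials_per_participant) == 1L) {
    trials_per_participant <- c(young = trials_per_participant[[1]],
                                old = trials_per_participant[[1]])
  }
  L <- arena$side_length
  groups <- c(rep("young", n_young), rep("old", n_old))
  ids <- sprintf("%s_%02d", groups, c(seq_len(n_young), seq_len(n_old)))

  trial_rows <- vector("list", length(ids))
  traj_rows <- vector("list", length(ids))
  par_rows <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    grp <- groups[i]
    seed_i <- derive_seed(rng_seed, i)
    n_trials <- as.integer(trials_per_participant[[grp]])
    res <- local_seed(seed_i, {
      pars <- individual_params(group_params[[grp]])
      tr_list <- vector("list", n_trials)
      tj_list <- vector("list", n_trials)
      # targets cycle in blocks of random order, as in the task
      order_idx <- unlist(lapply(seq_len(ceiling(n_trials / nrow(targets))),
                                 function(k) sample.int(nrow(targets))))[seq_len(n_trials)]
      for (j in seq_len(n_trials)) {
        tgt <- targets[order_idx[j], ]
        start <- stats::runif(2, 0.02 * L, 0.98 * L)
        resp <- simulate_response(c(tgt$x, tgt$y), pars, arena)
        seed_traj <- if (pars$boundary_attraction > 0) derive_seed(seed_i, j, 1L) else NULL
        traj <- simulate_trajectory(start, as.numeric(resp), pars, arena,
                                    rng_seed = seed_traj,
                                    start_heading = stats::runif(1, -180, 180))
        tr_list[[j]] <- data.frame(
          participant_id = ids[i], age_group = grp, trial_index = j,
          target = tgt$name, target_x = tgt$x, target_y = tgt$y,
          start_x = start[1], start_y = start[2],
          response_x = resp[1], response_y = resp[2],
          response_time = max(traj$t) + stats::runif(1, 0.3, 1.2),
          clipped = isTRUE(attr(resp, "clipped")),
          stringsAsFactors = FALSE)
        tj_list[[j]] <- cbind(participant_id = ids[i], trial_index = j,
                              as.data.frame(traj))
      }
      list(trials = do.call(rbind, tr_list),
           trajs = do.call(rbind, tj_list),
           pars = data.frame(participant_id = ids[i], age_group = grp,
                             lambda = pars$lambda,
                             boundary_attraction = pars$boundary_attraction,
                             sigma0 = pars$sigma0, sigma1 = pars$sigma1,
                             seed = seed_i, stringsAsFactors = FALSE))
    })
    trial_rows[[i]] <- res$trials
    traj_rows[[i]] <- res$trajs
    par_rows[[i]] <- res$pars
  }

  out <- list(trials = do.call(rbind, trial_rows),
              trajectories = do.call(rbind, traj_rows),
              params = do.call(rbind, par_rows),
              arena = arena, targets = targets, rng_seed = rng_seed)
  rownames(out$trials) <- rownames(out$trajectories) <- rownames(out$params) <- NULL
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d young, %d old), %d trials, %d trajectory samples\n",
              length(unique(x$trials$participant_id)),
              sum(x$params$age_group == "young"),
              sum(x$params$age_group == "old"),
              nrow(x$trials), nrow(x$trajectories)))
  invisible(x)
}
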