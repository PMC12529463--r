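#' Euclidean error of a response
#'
#' Straight-line distance between the response and the correct target
#' location, in vm. Vectorized over rows.
#'
#' @param response,target Positions: length-2 numerics, n x 2 matrices, or
#'   data frames with `x`/`y` columns.
#' @param arena An [arena()] (used for validation only).
#' @return Numeric vector of distances (vm).
#' @export
euclidean_error <- function(response, target, arena = boundnav::arena()) {
  r <- as_position_matrix(response, arena, "response")
  g <- as_position_matrix(target, arena, "target")
  stopifnot(nrow(r) == nrow(g))
  sqrt((r[, 1] - g[, 1])^2 + (r[, 2] - g[, 2])^2)
}

#' Feedback class for a trial error
#'
#' The task's smiley feedback: errors below 20 vm give a green smiley,
#' between 20 and 30 vm a yellow smiley, above 30 vm a red smiley. A trial
#' triggers re-encoding of the target (the object is shown again) whenever
#' the error exceeds 20 vm. At exactly 20 vm the feedback is yellow but no
#' re-encoding occurs (the rule is strictly "over 20").
#'
#' @param error Non-negative numeric vector of Euclidean errors (vm).
#' @param green_max Upper edge of the green band (exclusive), vm.
#' @param yellow_max Upper edge of the yellow band (inclusive), vm.
#' @return Data frame with columns `feedback` (factor green/yellow/red) and
#'   `reencode` (logical).
#' @export
feedback_class <- function(error, green_max = 20, yellow_max = 30) {
  if (any(!is.finite(error) | error < 0)) {
    stop("errors must be finite and non-negative", call. = FALSE)
  }
  fb <- ifelse(error < green_max, "green",
               ifelse(error <= yellow_max, "yellow", "red"))
  data.frame(feedback = factor(fb, levels = c("green", "yellow", "red")),
             reencode = error > green_max)
}

#' Boundary bias of a response
#'
#' Ratio of the correct location's wall distance to the response's wall
#' distance. The `two_wall` variant computes the per-axis nearer-wall
#' distance ratio separately for x and y and averages the two ratios; the
#' `nearest_wall` variant uses the single closest-wall distance. Values
#' above 1 indicate responses placed closer to boundaries than the target;
#' below 1, farther away. Response wall distances below 0.1 vm are clamped
#' before division (responses exactly on a wall), with a warning.
#'
#' @param target,response Positions (length-2, matrix, or data frame).
#' @param arena An [arena()].
#' @param variant `"two_wall"` (default) or `"nearest_wall"`.
#' @param warn Warn when denominator clamping occurs.
#' @return Numeric vector of bias ratios.
#' @export
boundary_bias <- function(target, response, arena = boundnav::arena(),
                          variant = c("two_wall", "nearest_wall"), warn = TRUE) {
  variant <- match.arg(variant)
  if (variant == "two_wall") {
    num_x <- axis_wall_distance(target, arena, "x")
    num_y <- axis_wall_distance(target, arena, "y")
    den_x <- clamp_denominator(axis_wall_distance(response, arena, "x"), warn = warn)
    den_y <- clamp_denominator(axis_wall_distance(response, arena, "y"), warn = FALSE)
    (num_x / den_x + num_y / den_y) / 2
  } else {
    num <- nearest_wall_distance(target, arena)
    den <- clamp_denominator(nearest_wall_distance(response, arena), warn = warn)
    num / den
  }
}

#' Boundary proximity index from wall-distance samples
#'
#' Core of the BPI: given per-sample nearer-wall distances along each axis
#' for the beeline and the actual path (translation samples only), computes
#' the per-axis ratio of the chosen central tendency (beeline / actual) and
#' averages the two ratios. Exposed separately so the index can be computed
#' on externally supplied distance lists.
#'
#' @param bee_x,bee_y Axis wall distances along the beeline.
#' @param act_x,act_y Axis wall distances along the actual path.
#' @param center `"median"` (default) or `"mean"`.
#' @param warn Warn on denominator clamping.
#' @return A single BPI ratio; > 1 means the actual path ran closer to
#'   boundaries than the beeline.
#' @export
bpi_from_wall_distances <- function(bee_x, bee_y, act_x, act_y,
                                    center = c("median", "mean"), warn = TRUE) {
  center <- match.arg(center)
  f <- if (center == "median") stats::median else mean
  den_x <- clamp_denominator(f(act_x), warn = warn)
  den_y <- clamp_denominator(f(act_y), warn = FALSE)
  (f(bee_x) / den_x + f(bee_y) / den_y) / 2
}

# Beeline from start to response, sampled at the same rate and speed as the
# recorded trajectory; returns translation samples only (matching the
# actual path's per-sample treatment).
beeline_translation_samples <- function(start, response, params, arena) {
  seg <- segment_samples(start, response, 0, params)
  keep <- seg$moving == "translation"
  cbind(x = seg$x[keep], y = seg$y[keep])
}

#' Boundary proximity index of a trial
#'
#' Compares how close to the walls the actual navigation path ran relative
#' to the ideal straight (beeline) path to the same response location. Both
#' paths are reduced to their translation samples; per axis, the central
#' tendency (median by default) of the nearer-wall distance is computed for
#' each path, the beeline value is divided by the actual value, and the two
#' axis ratios are averaged. BPI > 1 indicates navigation hugging the walls
#' more than the beeline; < 1, more central navigation.
#'
#' @param trajectory A `trajectory` data frame (columns `t`, `x`, `y`,
#'   `moving`).
#' @param start,response Trial start and response positions.
#' @param arena An [arena()].
#' @param center `"median"` (default) or `"mean"`.
#' @param params [agent_params()] supplying the sampling rate and speed for
#'   beeline construction (defaults match the task kinematics).
#' @param warn Warn on denominator clamping.
#' @return A single BPI value, or `NA` (with a warning) when the trajectory
#'   contains no translation samples.
#' @export
bpi <- function(trajectory, start, response, arena = boundnav::arena(),
                center = c("median", "mean"), params = agent_params(),
                warn = TRUE) {
  center <- match.arg(center)
  act <- trajectory[trajectory$moving == "translation", , drop = FALSE]
  if (nrow(act) == 0L) {
    warning("trajectory has no translation samples; BPI undefined", call. = FALSE)
    return(NA_real_)
  }
  start <- drop(as_position_matrix(start, arena, "start"))
  response <- drop(as_position_matrix(response, arena, "response"))
  bee <- beeline_translation_samples(start, response, params, arena)
  if (nrow(bee) == 0L) {
    # response within one sample step of start: beeline degenerates to the
    # start point itself
    bee <- matrix(start, ncol = 2, dimnames = list(NULL, c("x", "y")))
  }
  bpi_from_wall_distances(
    axis_wall_distance(bee, arena, "x"), axis_wall_distance(bee, arena, "y"),
    axis_wall_distance(cbind(act$x, act$y), arena, "x"),
    axis_wall_distance(cbind(act$x, act$y), arena, "y"),
    center = center, warn = warn
  )
}

#' Boundary occupancy of a trajectory
#'
#' Fraction of translation samples whose nearest-wall distance lies within
#' each given fraction of the arena side (default 5, 10 and 15 percent).
#'
#' @param trajectory A `trajectory` data frame.
#' @param arena An [arena()].
#' @param thresholds Fractions of `side_length` defining the boundary zone.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
boundary_occupancy <- function(trajectory, arena = boundnav::arena(),
                               thresholds = c(0.05, 0.10, 0.15)) {
  if (length(thresholds) == 0L) stop("`thresholds` must be non-empty", call. = FALSE)
  act <- trajectory[trajectory$moving == "translation", , drop = FALSE]
  if (nrow(act) == 0L) {
    warning("trajectory has no translation samples; occupancy undefined", call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(thresholds)),
                           sprintf("occ_%g", thresholds * 100)))
  }
  d <- nearest_wall_distance(cbind(act$x, act$y), arena)
  out <- vapply(thresholds, function(q) mean(d < q * arena$side_length), numeric(1))
  stats::setNames(out, sprintf("occ_%g", thresholds * 100))
}

#' Interquartile-range outlier filter
#'
#' Flags trials whose Euclidean error lies more than 1.5 x IQR below the
#' first or above the third quartile of that participant's own error
#' distribution. Quartiles use linear interpolation (`quantile` type 7);
#' the convention matters because it changes which trials survive.
#'
#' @param errors Numeric vector of one participant's trial errors.
#' @return List with `keep` (logical vector), `removed_fraction`, and the
#'   `bounds` used. With fewer than 4 trials the filter is skipped (all
#'   kept) with a warning.
#' @export
iqr_outlier_filter <- function(errors) {
  stopifnot(is.numeric(errors))
  if (length(errors) < 4L) {
    warning("fewer than 4 trials; IQR outlier filter skipped", call. = FALSE)
    return(list(keep = rep(TRUE, length(errors)), removed_fraction = 0,
                bounds = c(-Inf, Inf)))
  }
  q <- stats::quantile(errors, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  keep <- errors >= bounds[1] & errors <= bounds[2]
  list(keep = keep, removed_fraction = mean(!keep), bounds = bounds)
}

#' Score every trial of a cohort
#'
#' Computes the full per-trial metric set: Euclidean error, feedback class,
#' boundary bias (both wall-distance variants), BPI (median- and mean-based)
#' and boundary occupancy, plus the per-participant IQR outlier flag on
#' Euclidean error.
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a list with
#'   `trials` and `trajectories` data frames in the documented schema.
#' @param arena An [arena()].
#' @param params [agent_params()] used for beeline construction in BPI.
#' @param occupancy_thresholds Fractions of the arena side for
#'   [boundary_occupancy()].
#' @return The `trials` data frame augmented with metric columns
#'   (`error`, `feedback`, `reencode`, `bias_two_wall`, `bias_nearest_wall`,
#'   `bpi_median`, `bpi_mean`, `occ_*`, `outlier`).
#' @export
score_trials <- function(cohort, arena = cohort$arena %||% boundnav::arena(),
                         params = agent_params(),
                         occupancy_thresholds = c(0.05, 0.10, 0.15)) {
  trials <- cohort$trials
  trajs <- cohort$trajectories
  tg <- cbind(trials$target_x, trials$target_y)
  rs <- cbind(trials$response_x, trials$response_y)
  trials$error <- euclidean_error(rs, tg, arena)
  fb <- feedback_class(trials$error)
  trials$feedback <- fb$feedback
  trials$reencode <- fb$reencode
  trials$bias_two_wall <- boundary_bias(tg, rs, arena, "two_wall", warn = FALSE)
  trials$bias_nearest_wall <- boundary_bias(tg, rs, arena, "nearest_wall", warn = FALSE)

  key <- paste(trajs$participant_id, trajs$trial_index)
  traj_split <- split(seq_len(nrow(trajs)), key)
  occ_names <- sprintf("occ_%g", occupancy_thresholds * 100)
  bpi_med <- bpi_mean <- numeric(nrow(trials))
  occ <- matrix(NA_real_, nrow(trials), length(occupancy_thresholds),
                dimnames = list(NULL, occ_names))
  for (i in seq_len(nrow(trials))) {
    idx <- traj_split[[paste(trials$participant_id[i], trials$trial_index[i])]]
    tr <- trajs[idx, , drop = FALSE]
    st <- c(trials$start_x[i], trials$start_y[i])
    rp <- c(trials$response_x[i], trials$response_y[i])
    bpi_med[i] <- bpi(tr, st, rp, arena, "median", params, warn = FALSE)
    bpi_mean[i] <- bpi(tr, st, rp, arena, "mean", params, warn = FALSE)
    occ[i, ] <- boundary_occupancy(tr, arena, occupancy_thresholds)
  }
  trials$bpi_median <- bpi_med
  trials$bpi_mean <- bpi_mean
  trials <- cbind(trials, as.data.frame(occ))

  trials$outlier <- FALSE
  for (pid in unique(trials$participant_id)) {
    sel <- trials$participant_id == pid
    flt <- iqr_outlier_filter(trials$error[sel])
    trials$outlier[sel] <- !flt$keep
  }
  trials
}

#' Per-participant metric summaries
#'
#' Aggregates filtered trial metrics to one record per participant x target
#' plus an overall per-participant record (`target = "all"`), each with the
#' mean and median of every metric. Bias and BPI aggregate as the
#' per-participant mean of per-trial values.
#'
#' @param scored A scored trial table from [score_trials()]; rows flagged
#'   `outlier` are excluded.
#' @param metrics Character vector of metric columns to summarise.
#' @return Data frame ordered by participant then target, with `n_trials`
#'   and `<metric>_mean` / `<metric>_median` columns. Participants with
#'   zero retained trials are flagged with `n_trials = 0`.
#' @export
participant_summary <- function(scored,
                                metrics = c("error", "bias_two_wall",
                                            "bias_nearest_wall", "bpi_median",
                                            "bpi_mean")) {
  keep <- scored[!scored$outlier, , drop = FALSE]
  all_pid <- unique(scored$participant_id)
  rows <- list()
  for (pid in all_pid) {
    sub <- keep[keep$participant_id == pid, , drop = FALSE]
    grp <- scored$age_group[match(pid, scored$participant_id)]
    cells <- c(split(sub, sub$target), list(all = sub))
    for (tname in names(cells)) {
      cell <- cells[[tname]]
      rec <- data.frame(participant_id = pid, age_group = grp, target = tname,
                        n_trials = nrow(cell), stringsAsFactors = FALSE)
      for (m in metrics) {
        v <- cell[[m]]
        rec[[paste0(m, "_mean")]] <- if (nrow(cell)) mean(v, na.rm = TRUE) else NA_real_
        rec[[paste0(m, "_median")]] <- if (nrow(cell)) stats::median(v, na.rm = TRUE) else NA_real_
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate two metrics within groups
#'
#' Pearson correlation with a two-sided p-value between two columns of a
#' per-participant table, computed separately within each level of the
#' grouping column(s).
#'
#' @param table Data frame of per-participant values.
#' @param metric_a,metric_b Column names to correlate.
#' @param grouping Character vector of grouping columns (e.g.
#'   `c("age_group", "target")`); `NULL` for a single overall correlation.
#' @return Data frame with one row per group cell: `n`, `r`, `p`.
#'   Zero-variance cells report `NA` with `note = "zero variance"`.
#' @export
metric_correlation <- function(table, metric_a, metric_b, grouping = NULL) {
  cells <- if (is.null(grouping)) list(all = table) else {
    split(table, table[grouping], drop = TRUE, sep = ":")
  }
  rows <- lapply(names(cells), function(nm) {
    cell <- cells[[nm]]
    a <- cell[[metric_a]]; b <- cell[[metric_b]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(group = nm, n = length(a), r = NA_real_, p = NA_real_,
                        note = if (length(a) >= 3) "zero variance" else "n < 3",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    data.frame(group = nm, n = length(a), r = unname(ct$estimate),
               p = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
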