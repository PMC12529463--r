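#' Navigation-agent parameters
#'
#' Parameters of the synthetic navigator and its response model. The
#' kinematic constants match the task: translation at a constant 15 vm/s,
#' rotation at 50 deg/s, and no translation while rotating, so every path is
#' a sequence of straight segments. The response model implements a
#' category-adjustment style account of spatial recall: each response
#' coordinate is displaced toward its nearer wall by fraction `lambda` of
#' the axis wall distance, then perturbed by Gaussian noise whose standard
#' deviation grows linearly with the target's summed two-wall distance
#' (`sigma0 + sigma1 * d`), capturing the loss of precision away from
#' boundaries. `boundary_attraction` bends navigation paths toward the
#' nearest wall via a displaced intermediate waypoint.
#'
#' @param translation_speed Translation speed in vm/s (default 15).
#' @param rotation_speed Rotation speed in deg/s (default 50).
#' @param sampling_rate Trajectory sampling rate in Hz (default 10).
#' @param boundary_attraction Strength of wall-directed path bending, in
#'   `[0, 1]`; 0 gives pure beelines.
#' @param lambda Fractional displacement of responses toward the nearer
#'   wall per axis, in `[0, 1]`.
#' @param sigma0 Baseline response noise SD in vm.
#' @param sigma1 Increase in response noise SD per vm of the target's
#'   summed two-wall distance.
#' @param lambda_sd,attraction_sd Between-participant SDs used by
#'   [simulate_cohort()] when drawing individual parameter values
#'   (truncated to the legal range).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(translation_speed = 15,
                         rotation_speed = 50,
                         sampling_rate = 10,
                         boundary_attraction = 0,
                         lambda = 0,
                         sigma0 = 2,
                         sigma1 = 0.02,
                         lambda_sd = 0,
                         attraction_sd = 0) {
  stopifnot(
    translation_speed > 0, rotation_speed > 0, sampling_rate > 0,
    boundary_attraction >= 0, boundary_attraction <= 1,
    lambda >= 0, lambda <= 1,
    sigma0 >= 0, sigma1 >= 0, lambda_sd >= 0, attraction_sd >= 0
  )
  structure(list(
    translation_speed = translation_speed,
    rotation_speed = rotation_speed,
    sampling_rate = sampling_rate,
    boundary_attraction = boundary_attraction,
    lambda = lambda,
    sigma0 = sigma0,
    sigma1 = sigma1,
    lambda_sd = lambda_sd,
    attraction_sd = attraction_sd
  ), class = "agent_params")
}

#' Default group parameter sets
#'
#' Parameter sets for the two age groups, calibrated by Monte Carlo so that
#' the young cohort shows essentially unbiased responses (mean boundary bias
#' within 0.95-1.05) while the old cohort is pulled toward walls (mean bias
#' above 1.05) with steeper distance-dependent error and stronger path
#' attraction to boundaries.
#'
#' @return Named list with elements `young` and `old`, each an
#'   [agent_params()].
#' @export
default_group_params <- function() {
  list(
    young = agent_params(boundary_attraction = 0.10, lambda = 0,
                         sigma0 = 2, sigma1 = 0.02,
                         lambda_sd = 0.01, attraction_sd = 0.05),
    old = agent_params(boundary_attraction = 0.35, lambda = 0.12,
                       sigma0 = 3, sigma1 = 0.05,
                       lambda_sd = 0.05, attraction_sd = 0.15)
  )
}

# One trajectory segment: rotate in place toward `goal`, then translate in a
# straight line at constant speed. Samples lie on the global 1/fs grid; the
# translation stops at the last on-grid point not beyond the goal, so the
# endpoint is within one sample step of the goal.
segment_samples <- function(from, goal, heading, params) {
  fs <- params$sampling_rate
  dt <- 1 / fs
  dx <- goal[1] - from[1]
  dy <- goal[2] - from[2]
  dist <- sqrt(dx^2 + dy^2)
  target_heading <- if (dist > 0) atan2(dy, dx) * 180 / pi else heading
  delta <- ((target_heading - heading + 180) %% 360) - 180

  out_t <- numeric(0); out_x <- numeric(0); out_y <- numeric(0)
  out_h <- numeric(0); out_m <- character(0)

  n_rot <- ceiling(abs(delta) / (params$rotation_speed * dt))
  if (n_rot > 0) {
    step <- sign(delta) * params$rotation_speed * dt
    h <- heading + step * seq_len(n_rot)
    # final (possibly partial) step lands exactly on the target heading
    h[n_rot] <- target_heading
    out_t <- c(out_t, dt * seq_len(n_rot))
    out_x <- c(out_x, rep(from[1], n_rot))
    out_y <- c(out_y, rep(from[2], n_rot))
    out_h <- c(out_h, h)
    out_m <- c(out_m, rep("rotation", n_rot))
  }

  n_tr <- floor(dist / (params$translation_speed * dt))
  if (n_tr > 0) {
    frac <- params$translation_speed * dt * seq_len(n_tr) / dist
    out_t <- c(out_t, dt * (n_rot + seq_len(n_tr)))
    out_x <- c(out_x, from[1] + dx * frac)
    out_y <- c(out_y, from[2] + dy * frac)
    out_h <- c(out_h, rep(target_heading, n_tr))
    out_m <- c(out_m, rep("translation", n_tr))
  }

  list(t = out_t, x = out_x, y = out_y, heading = out_h, moving = out_m,
       end = if (n_tr > 0) c(utils::tail(out_x, 1), utils::tail(out_y, 1)) else from,
       end_heading = target_heading)
}

# Waypoint for boundary-attracted paths: a point part-way along the beeline,
# displaced toward its nearest wall by a random fraction proportional to the
# attraction parameter.
attracted_waypoint <- function(start, goal, attraction, arena) {
  L <- arena$side_length
  u <- stats::runif(1, 0.35, 0.65)
  m <- start + u * (goal - start)
  frac <- attraction * stats::runif(1, 0.5, 1)
  dists <- c(m[1], L - m[1], m[2], L - m[2])
  k <- which.min(dists)
  if (k == 1L) m[1] <- m[1] * (1 - frac)
  if (k == 2L) m[1] <- L - (L - m[1]) * (1 - frac)
  if (k == 3L) m[2] <- m[2] * (1 - frac)
  if (k == 4L) m[2] <- L - (L - m[2]) * (1 - frac)
  m
}

#' Simulate one rotate-then-translate trajectory
#'
#' Generates a trajectory from `start` to `goal` obeying the task
#' kinematics: the agent first rotates in place toward its (next) waypoint
#' at the fixed rotation speed, then translates along a straight line at the
#' fixed translation speed; position changes only during translation and
#' heading only during rotation. With `boundary_attraction = 0` the path is
#' the single straight beeline; with positive attraction one intermediate
#' waypoint is displaced toward the nearest wall, so the realized path hugs
#' the boundary more than the beeline does.
#'
#' @param start,goal Positions inside the arena (length-2 numerics).
#' @param params An [agent_params()].
#' @param arena An [arena()].
#' @param rng_seed Integer seed; required when `boundary_attraction > 0`
#'   (the waypoint is stochastic). `NULL` draws from the current RNG stream
#'   only when the path is deterministic.
#' @param start_heading Initial heading in degrees (default 0).
#' @return A data frame of class `trajectory` with columns `t`, `x`, `y`,
#'   `heading`, `moving` (one of `"stationary"`, `"rotation"`,
#'   `"translation"`), sampled on a regular `1/sampling_rate` grid and
#'   ending within one sample step of `goal`.
#' @export
simulate_trajectory <- function(start, goal, params = agent_params(),
                                arena = boundnav::arena(), rng_seed = NULL,
                                start_heading = 0) {
  start <- drop(as_position_matrix(start, arena, "start"))
  goal <- drop(as_position_matrix(goal, arena, "goal"))
  if (params$boundary_attraction > 0 && is.null(rng_seed)) {
    stop("`rng_seed` is required when boundary_attraction > 0", call. = FALSE)
  }
  local_seed(rng_seed, {
    waypoints <- if (params$boundary_attraction > 0) {
      list(attracted_waypoint(start, goal, params$boundary_attraction, arena), goal)
    } else {
      list(goal)
    }
    t0 <- 0
    pos <- start
    heading <- start_heading
    parts <- list(data.frame(t = 0, x = start[1], y = start[2],
                             heading = start_heading, moving = "stationary",
                             stringsAsFactors = FALSE))
    for (w in waypoints) {
      seg <- segment_samples(pos, w, heading, params)
      if (length(seg$t)) {
        parts[[length(parts) + 1L]] <- data.frame(
          t = t0 + seg$t, x = seg$x, y = seg$y,
          heading = seg$heading, moving = seg$moving, stringsAsFactors = FALSE)
        t0 <- t0 + utils::tail(seg$t, 1)
      }
      pos <- seg$end
      heading <- seg$end_heading
    }
    traj <- do.call(rbind, parts)
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}

#' Simulate a continuous navigation session
#'
#' Chains trajectory legs to successive random goals, separated by short
#' stationary response pauses, until the requested duration is covered.
#' Used as the movement stream behind simulated BOLD runs.
#'
#' @param duration Session length in seconds.
#' @param params An [agent_params()].
#' @param arena An [arena()].
#' @param rng_seed Integer seed.
#' @param pause_range Range (s) of the stationary pause after each leg.
#' @return A `trajectory` data frame spanning at least `duration` seconds.
#' @export
simulate_session <- function(duration, params = agent_params(),
                             arena = boundnav::arena(), rng_seed = 1L,
                             pause_range = c(1.5, 3.5)) {
  stopifnot(duration > 0)
  fs <- params$sampling_rate
  dt <- 1 / fs
  local_seed(rng_seed, {
    L <- arena$side_length
    pos <- stats::runif(2, 0.1 * L, 0.9 * L)
    heading <- stats::runif(1, -180, 180)
    t0 <- 0
    parts <- list(data.frame(t = 0, x = pos[1], y = pos[2], heading = heading,
                             moving = "stationary", stringsAsFactors = FALSE))
    while (t0 < duration) {
      goal <- stats::runif(2, 0.05 * L, 0.95 * L)
      waypoints <- if (params$boundary_attraction > 0) {
        list(attracted_waypoint(pos, goal, params$boundary_attraction, arena), goal)
      } else list(goal)
      for (w in waypoints) {
        seg <- segment_samples(pos, w, heading, params)
        if (length(seg$t)) {
          parts[[length(parts) + 1L]] <- data.frame(
            t = t0 + seg$t, x = seg$x, y = seg$y,
            heading = seg$heading, moving = seg$moving, stringsAsFactors = FALSE)
          t0 <- t0 + utils::tail(seg$t, 1)
        }
        pos <- seg$end
        heading <- seg$end_heading
      }
      n_pause <- round(stats::runif(1, pause_range[1], pause_range[2]) * fs)
      if (n_pause > 0) {
        parts[[length(parts) + 1L]] <- data.frame(
          t = t0 + dt * seq_len(n_pause), x = pos[1], y = pos[2],
          heading = heading, moving = "stationary", stringsAsFactors = FALSE)
        t0 <- t0 + dt * n_pause
      }
    }
    traj <- do.call(rbind, parts)
    traj <- traj[traj$t <= duration + dt / 2, , drop = FALSE]
    rownames(traj) <- NULL
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}

#' Simulate a remembered-location response
#'
#' Category-adjustment style response model: per axis the target coordinate
#' is displaced toward its nearer wall by fraction `lambda` of the axis wall
#' distance, then perturbed by centered Gaussian noise with SD
#' `sigma0 + sigma1 * two_wall_distance_sum(target)`. Responses falling
#' outside the arena are clipped to its walls (and flagged).
#'
#' @param target Target position (length-2 numeric).
#' @param params An [agent_params()].
#' @param arena An [arena()].
#' @param rng_seed Integer seed, or `NULL` for the current stream.
#' @return Length-2 numeric response position, with attribute `clipped`
#'   (logical) marking whether arena clipping occurred.
#' @export
simulate_response <- function(target, params = agent_params(),
                              arena = boundnav::arena(), rng_seed = NULL) {
  target <- drop(as_position_matrix(target, arena, "target"))
  L <- arena$side_length
  local_seed(rng_seed, {
    displaced <- vapply(target, function(cc) {
      if (cc <= L / 2) cc * (1 - params$lambda) else L - (L - cc) * (1 - params$lambda)
    }, numeric(1))
    sd_resp <- params$sigma0 + params$sigma1 * two_wall_distance_sum(target, arena)
    resp <- displaced + stats::rnorm(2, 0, sd_resp)
    clipped <- any(resp < 0 | resp > L)
    resp <- pmin(pmax(resp, 0), L)
    attr(resp, "clipped") <- clipped
    resp
  })
}
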