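path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

test_that("attraction-free trajectories are straight constant-speed beelines", {
  p <- agent_params()
  tr <- simulate_trajectory(c(80, 80), c(40, 40), p)
  # all translation samples lie on the start-goal line
  mv <- tr[tr$moving == "translation", ]
  expect_gt(nrow(mv), 0)
  cross <- (mv$x - 80) * (40 - 80) - (mv$y - 80) * (40 - 80)
  expect_true(all(abs(cross) < 1e-9))
  # BPI against its own beeline is exactly 1
  expect_equal(bpi(tr, c(80, 80), c(40, 40)), 1)
  # translation duration equals distance / speed within one sample
  dist <- sqrt(2) * 40
  n_tr <- sum(tr$moving == "translation")
  expect_lt(abs(n_tr / p$sampling_rate - dist / p$translation_speed),
            1 / p$sampling_rate + 1e-9)
  # endpoint within one sample step of the goal
  end <- tr[nrow(tr), ]
  expect_lt(sqrt((end$x - 40)^2 + (end$y - 40)^2),
            p$translation_speed / p$sampling_rate + 1e-9)
})

test_that("kinematic invariants hold: regular grid, motion-state exclusivity", {
  p <- agent_params(boundary_attraction = 0.6)
  tr <- simulate_trajectory(c(20, 140), c(120, 30), p, rng_seed = 5)
  expect_equal(diff(tr$t), rep(1 / p$sampling_rate, nrow(tr) - 1),
               tolerance = 1e-9)
  # position changes only during translation
  moved <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) > 1e-12
  expect_true(all(tr$moving[-1][moved] == "translation"))
  # heading changes only during rotation
  turned <- abs(diff(tr$heading)) > 1e-12
  expect_true(all(tr$moving[-1][turned] == "rotation"))
  # integrated path length equals speed x translation time within one sample
  n_tr <- sum(tr$moving == "translation")
  expect_lt(abs(path_length(tr) - p$translation_speed * n_tr / p$sampling_rate),
            p$translation_speed / p$sampling_rate + 1e-9)
})

test_that("boundary attraction pulls paths toward walls over many seeds", {
  p0 <- agent_params(boundary_attraction = 0)
  p8 <- agent_params(boundary_attraction = 0.8)
  a <- arena()
  med_wall <- function(tr) {
    mv <- tr[tr$moving == "translation", ]
    median(nearest_wall_distance(cbind(mv$x, mv$y), a))
  }
  m0 <- m8 <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    st <- runif(2, 30, 130); gl <- runif(2, 30, 130)
    m0[s] <- med_wall(simulate_trajectory(st, gl, p0))
    m8[s] <- med_wall(simulate_trajectory(st, gl, p8, rng_seed = s))
  }
  expect_lt(mean(m8), mean(m0))
})

test_that("a seed is required for stochastic paths, and fixed seeds reproduce", {
  p <- agent_params(boundary_attraction = 0.5)
  expect_error(simulate_trajectory(c(10, 10), c(100, 100), p),
               "rng_seed")
  t1 <- simulate_trajectory(c(10, 10), c(100, 100), p, rng_seed = 9)
  t2 <- simulate_trajectory(c(10, 10), c(100, 100), p, rng_seed = 9)
  expect_identical(t1, t2)
})

test_that("sessions cover the requested duration with valid samples", {
  p <- agent_params(boundary_attraction = 0.3)
  s <- simulate_session(60, p, rng_seed = 3)
  expect_gte(max(s$t), 60 - 1 / p$sampling_rate)
  expect_true(all(s$x >= 0 & s$x <= 160 & s$y >= 0 & s$y <= 160))
  expect_true(all(s$moving %in% c("stationary", "rotation", "translation")))
  expect_true(all(diff(s$t) > 0))
})

test_that("noiseless unbiased responses reproduce the target exactly", {
  p <- agent_params(lambda = 0, sigma0 = 0, sigma1 = 0)
  r <- simulate_response(c(33, 16), p, rng_seed = 1)
  expect_equal(as.numeric(r), c(33, 16))
  expect_equal(boundary_bias(c(33, 16), as.numeric(r)), 1)
})

test_that("wall displacement makes boundary bias exceed 1 deterministically", {
  p <- agent_params(lambda = 0.2, sigma0 = 0, sigma1 = 0)
  for (tgt in list(c(33, 16), c(27, 69), c(64, 38), c(100, 120))) {
    r <- simulate_response(tgt, p, rng_seed = 1)
    expect_gt(boundary_bias(tgt, as.numeric(r)), 1)
  }
})

test_that("response error grows with the target's boundary distance", {
  p <- agent_params(lambda = 0, sigma0 = 2, sigma1 = 0.05)
  tg <- default_targets()
  mean_err <- vapply(seq_len(3), function(i) {
    tgt <- c(tg$x[i], tg$y[i])
    errs <- withr::with_seed(100 + i, vapply(seq_len(10000), function(j) {
      r <- simulate_response(tgt, p)
      sqrt(sum((as.numeric(r) - tgt)^2))
    }, numeric(1)))
    mean(errs)
  }, numeric(1))
  names(mean_err) <- tg$name
  expect_lt(mean_err["trash_bin"], mean_err["plant"])
  expect_lte(mean_err["plant"], mean_err["ball"])
})

test_that("response noise and displacement scale monotonically", {
  tgt <- c(64, 38)
  draw_err <- function(p, seed) {
    withr::with_seed(seed, mean(vapply(seq_len(2000), function(j) {
      r <- simulate_response(tgt, p)
      sqrt(sum((as.numeric(r) - tgt)^2))
    }, numeric(1))))
  }
  e_small <- draw_err(agent_params(sigma0 = 1, sigma1 = 0), 1)
  e_large <- draw_err(agent_params(sigma0 = 4, sigma1 = 0), 1)
  expect_lt(e_small, e_large)
  e_flat <- draw_err(agent_params(sigma0 = 2, sigma1 = 0), 2)
  e_slope <- draw_err(agent_params(sigma0 = 2, sigma1 = 0.05), 2)
  expect_lt(e_flat, e_slope)
  # bias is non-decreasing in lambda
  draw_bias <- function(lam, seed) {
    withr::with_seed(seed, mean(vapply(seq_len(2000), function(j) {
      r <- simulate_response(tgt, agent_params(lambda = lam, sigma0 = 2))
      boundary_bias(tgt, as.numeric(r), warn = FALSE)
    }, numeric(1))))
  }
  expect_lt(draw_bias(0, 3), draw_bias(0.15, 3))
})
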