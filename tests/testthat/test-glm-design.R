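make_traj <- function(t, x, y, moving) {
  data.frame(t = t, x = x, y = y, heading = 0, moving = moving,
             stringsAsFactors = FALSE)
}

test_that("TR windows pick up translation events under the any-sample rule", {
  cfg <- scan_config(run_duration = 9)  # 6 TRs
  tt <- seq(0, 8.9, 0.1)
  moving <- rep("stationary", length(tt))
  moving[tt >= 1.5 & tt < 4.5] <- "translation"  # TRs 2 and 3
  tr <- make_traj(tt, 80, 80, moving)
  ev <- translation_tr_events(tr, cfg)
  expect_equal(ev$volume, c(2, 3))
  expect_equal(ev$fraction, c(1, 1))
})

test_that("one brief translation marks its TR with the right fraction", {
  cfg <- scan_config(run_duration = 12)
  tt <- seq(0, 11.9, 0.1)
  moving <- rep("stationary", length(tt))
  moving[abs(tt - 6.5) < 0.001] <- "translation"  # one 0.1-s sample in TR 5
  ev <- translation_tr_events(make_traj(tt, 80, 80, moving), cfg)
  expect_equal(ev$volume, 5)
  expect_equal(ev$fraction, 0.1 / 1.5, tolerance = 1e-9)
})

test_that("a stationary run has no events and the design build refuses", {
  cfg <- scan_config(run_duration = 9)
  tt <- seq(0, 8.9, 0.1)
  tr <- make_traj(tt, 80, 80, "stationary")
  ev <- translation_tr_events(tr, cfg)
  expect_equal(nrow(ev), 0)
  expect_error(build_design(ev, numeric(0), cfg = cfg), "no translation events")
  expect_error(pmod_series(tr, ev, cfg = cfg), "no translation events")
})

test_that("trajectories shorter than the run are rejected", {
  cfg <- scan_config(run_duration = 60)
  tr <- make_traj(seq(0, 9.9, 0.1), 80, 80, "translation")
  expect_error(translation_tr_events(tr, cfg), "does not span")
})

test_that("the modulator is the summed per-axis mean wall distance per window", {
  cfg <- scan_config(run_duration = 3)
  # parked at the trash-bin position: modulator equals its two-wall sum
  tt <- seq(0, 2.9, 0.1)
  tr <- make_traj(tt, 33, 16, ifelse(tt < 1.5, "translation", "stationary"))
  ev <- translation_tr_events(tr, cfg)
  expect_equal(pmod_series(tr, ev, cfg = cfg), 49)
  # hand arithmetic: x in {10, 20, 30}, y = 10 -> mean_x 20 + mean_y 10 = 30
  tt2 <- c(0, 0.5, 1.0)
  tr2 <- make_traj(tt2, c(10, 20, 30), 10, "translation")
  ev2 <- translation_tr_events(tr2, scan_config(run_duration = 1.5))
  expect_equal(pmod_series(tr2, ev2, cfg = scan_config(run_duration = 1.5)), 30)
  # parked at the arena center: maximal value L
  tr3 <- make_traj(tt, 80, 80, ifelse(tt < 1.5, "translation", "stationary"))
  ev3 <- translation_tr_events(tr3, cfg)
  expect_equal(pmod_series(tr3, ev3, cfg = cfg), 160)
})

test_that("the HRF kernel is causal, linear, and peaks near 6 s", {
  cfg <- scan_config()
  expect_equal(hrf_convolve(rep(0, 100), cfg), rep(0, 100))
  set.seed(61)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(hrf_convolve(a + b, cfg),
               hrf_convolve(a, cfg) + hrf_convolve(b, cfg), tolerance = 1e-10)
  imp <- c(1, rep(0, 99))
  resp <- hrf_convolve(imp, cfg)
  peak_t <- (which.max(resp) - 1) * cfg$tr
  expect_lte(abs(peak_t - 6), cfg$tr)
  # causality: nothing before the impulse
  shifted <- c(rep(0, 10), 1, rep(0, 89))
  expect_equal(hrf_convolve(shifted, cfg)[1:10], rep(0, 10))
})

test_that("the DCT drift set has the stated size and filtering behavior", {
  cfg <- scan_config()
  dct <- dct_highpass_set(640, cfg)
  expect_equal(ncol(dct), 15)  # floor(2 * 960 / 128)
  expect_equal(crossprod(dct), diag(15), tolerance = 1e-9,
               ignore_attr = TRUE)
  # projection residuals: constant fully removed by intercept + DCT
  X <- cbind(1, dct)
  P <- X %*% solve(crossprod(X), t(X))
  const <- rep(3, 640)
  expect_lt(sum(((diag(640) - P) %*% const)^2) / sum(const^2), 1e-6)
  tt <- (0:639) * 1.5
  slow <- sin(2 * pi * tt / 256)
  fast <- sin(2 * pi * tt / 32)
  res_slow <- slow - P %*% slow
  res_fast <- fast - P %*% fast
  expect_lt(sum(res_slow^2) / sum(slow^2), 0.10)   # >= 90% power removed
  expect_gt(sum(res_fast^2) / sum(fast^2), 0.90)   # <= 10% removed
})

test_that("design assembly centers the modulator and is deterministic", {
  cfg <- scan_config(run_duration = 60)
  ev <- data.frame(volume = c(5, 12), fraction = 1)
  X <- build_design(ev, c(40, 60), cfg = cfg)
  expect_equal(unname(attr(X, "pmod_centered")), c(-10, 10))
  X2 <- build_design(ev, c(40, 60), cfg = cfg)
  expect_identical(unclass(X), unclass(X2))
  expect_equal(colnames(X)[1:2], c("condition", "pmod"))
  expect_equal(colnames(X)[ncol(X)], "intercept")
  # a constant modulator is inestimable
  expect_error(build_design(ev, c(50, 50), cfg = cfg), "inestimable")
})

test_that("rank-deficient designs fail naming the collinear columns", {
  cfg <- scan_config(run_duration = 60)
  ev <- data.frame(volume = c(5, 12, 20), fraction = 1)
  motion <- matrix(rnorm(40 * 6), 40, 6)
  motion[, 2] <- motion[, 1]  # exact collinearity
  expect_error(build_design(ev, c(40, 60, 80), motion = motion, cfg = cfg),
               "collinear")
})
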