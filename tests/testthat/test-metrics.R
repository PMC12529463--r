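test_that("euclidean error matches hand arithmetic", {
  expect_equal(euclidean_error(c(33, 16), c(33, 16)), 0)
  expect_equal(euclidean_error(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_error(c(40, 20), c(33, 16)), sqrt(65))
})

test_that("feedback bands and the re-encode rule follow the task conventions", {
  fb <- feedback_class(c(10, 25, 20, 30, 31, 0))
  expect_equal(as.character(fb$feedback),
               c("green", "yellow", "yellow", "yellow", "red", "green"))
  expect_equal(fb$reencode, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(feedback_class(-1), "non-negative")
})

test_that("boundary bias reproduces hand-computed ratios in both variants", {
  expect_equal(boundary_bias(c(33, 16), c(33, 16)), 1)
  expect_equal(boundary_bias(c(33, 16), c(30, 12)), (33 / 30 + 16 / 12) / 2)
  expect_equal(boundary_bias(c(33, 16), c(40, 20)), 0.8125)
  expect_equal(boundary_bias(c(33, 16), c(30, 12), variant = "nearest_wall"),
               16 / 12)
  # responses on a wall clamp the denominator with a warning
  expect_warning(b <- boundary_bias(c(33, 16), c(0, 16)), "clamped")
  expect_equal(b, (33 / 0.1 + 16 / 16) / 2)
})

test_that("moving a response toward its nearer wall raises the two-wall bias", {
  set.seed(31)
  for (i in 1:25) {
    tgt <- runif(2, 10, 150)
    resp <- runif(2, 10, 150)
    b0 <- boundary_bias(tgt, resp, warn = FALSE)
    nearer_step <- if (resp[1] <= 80) -1 else 1
    resp2 <- resp + c(nearer_step, 0)
    expect_gt(boundary_bias(tgt, resp2, warn = FALSE), b0)
  }
})

test_that("BPI reproduces the fixed-sample hand example and identities", {
  expect_equal(
    bpi_from_wall_distances(rep(80, 5), c(40, 50, 60, 70, 80),
                            rep(80, 5), c(20, 25, 30, 35, 40), "median"),
    mean(c(80 / 80, 60 / 30)))
  # identical paths give exactly 1 for both center choices
  tr <- simulate_trajectory(c(100, 100), c(30, 40))
  expect_equal(bpi(tr, c(100, 100), c(30, 40), center = "median"), 1)
  expect_equal(bpi(tr, c(100, 100), c(30, 40), center = "mean"), 1)
})

test_that("BPI is invariant under uniform temporal resampling of both paths", {
  bee_x <- c(70, 72, 74, 76); bee_y <- c(30, 35, 40, 45)
  act_x <- c(60, 64, 68, 70); act_y <- c(10, 12, 14, 16)
  rep3 <- function(v) rep(v, each = 3)
  for (ctr in c("median", "mean")) {
    expect_equal(
      bpi_from_wall_distances(bee_x, bee_y, act_x, act_y, ctr),
      bpi_from_wall_distances(rep3(bee_x), rep3(bee_y),
                              rep3(act_x), rep3(act_y), ctr))
  }
})

test_that("trajectories without translation yield flagged undefined metrics", {
  still <- data.frame(t = c(0, 0.1), x = c(50, 50), y = c(50, 50),
                      heading = c(0, 10), moving = c("stationary", "rotation"))
  expect_warning(v <- bpi(still, c(50, 50), c(50, 50)), "no translation")
  expect_true(is.na(v))
  expect_warning(o <- boundary_occupancy(still), "no translation")
  expect_true(all(is.na(o)))
})

test_that("boundary occupancy matches pinned paths and a hand count", {
  wall_path <- data.frame(t = seq(0, 0.9, 0.1), x = seq(10, 19, 1), y = rep(2, 10),
                          heading = 0, moving = "translation")
  expect_equal(unname(boundary_occupancy(wall_path)), c(1, 1, 1))
  center_path <- data.frame(t = seq(0, 0.9, 0.1), x = rep(80, 10), y = rep(80, 10),
                            heading = 0, moving = "translation")
  expect_equal(unname(boundary_occupancy(center_path)), c(0, 0, 0))
  # hand count: nearest-wall distances 2,4,...,20; 5% of 160 = 8 -> 3 of 10
  graded <- data.frame(t = seq(0, 0.9, 0.1), x = rep(80, 10), y = seq(2, 20, 2),
                       heading = 0, moving = "translation")
  expect_equal(unname(boundary_occupancy(graded)),
               c(3 / 10, 7 / 10, 10 / 10))
  expect_error(boundary_occupancy(graded, thresholds = numeric(0)), "non-empty")
})

test_that("IQR filter reproduces hand quartile arithmetic and degenerate cases", {
  f1 <- iqr_outlier_filter(c(5, 6, 7, 8))
  expect_true(all(f1$keep))
  f2 <- iqr_outlier_filter(c(5, 5, 6, 6, 7, 7, 8, 8, 60))
  expect_equal(f2$keep, c(rep(TRUE, 8), FALSE))
  expect_equal(f2$removed_fraction, 1 / 9)
  f3 <- iqr_outlier_filter(rep(4, 6))
  expect_true(all(f3$keep))
  expect_warning(f4 <- iqr_outlier_filter(c(1, 2, 3)), "skipped")
  expect_true(all(f4$keep))
})

test_that("the IQR filter is idempotent on fixture error sets", {
  set.seed(41)
  fixtures <- list(
    c(rnorm(20, 10, 2), 60, 80), runif(12, 0, 30),
    c(rep(5, 10), 40), rlnorm(25, 1.5, 0.6), rnorm(30, 8, 3))
  for (errs in fixtures) {
    f1 <- iqr_outlier_filter(errs)
    kept <- errs[f1$keep]
    f2 <- iqr_outlier_filter(kept)
    expect_true(all(f2$keep), info = "second pass removes nothing")
  }
})

test_that("scored trial metrics agree with naive brute-force recomputation", {
  co <- simulate_cohort(3, 3, trials_per_participant = 9, rng_seed = 90)
  sc <- score_trials(co)
  a <- arena()
  p <- agent_params()
  idx <- withr::with_seed(7, sample(nrow(sc), 50))
  for (i in idx) {
    tgt <- c(sc$target_x[i], sc$target_y[i])
    rsp <- c(sc$response_x[i], sc$response_y[i])
    expect_equal(sc$error[i], sqrt(sum((tgt - rsp)^2)), tolerance = 1e-10)
    expect_equal(sc$bias_two_wall[i],
                 oracle_boundary_bias_two_wall(tgt, rsp, 160), tolerance = 1e-10)
    tj <- co$trajectories[co$trajectories$participant_id == sc$participant_id[i] &
                            co$trajectories$trial_index == sc$trial_index[i], ]
    act <- as.matrix(tj[tj$moving == "translation", c("x", "y")])
    # oracle beeline: explicit loop placing points every speed/fs vm
    st <- c(sc$start_x[i], sc$start_y[i])
    dist <- sqrt(sum((rsp - st)^2))
    step <- p$translation_speed / p$sampling_rate
    ks <- seq_len(floor(dist / step))
    bee <- if (length(ks)) {
      t(vapply(ks, function(k) st + (rsp - st) * k * step / dist, numeric(2)))
    } else matrix(st, ncol = 2)
    expect_equal(sc$bpi_median[i], oracle_bpi(bee, act, 160, "median"),
                 tolerance = 1e-10)
    expect_equal(sc$bpi_mean[i], oracle_bpi(bee, act, 160, "mean"),
                 tolerance = 1e-10)
    expect_equal(unname(sc$occ_5[i]), oracle_occupancy(act, 160, 0.05),
                 tolerance = 1e-10)
    expect_equal(unname(sc$occ_15[i]), oracle_occupancy(act, 160, 0.15),
                 tolerance = 1e-10)
  }
})

test_that("participant summaries aggregate trials as stated", {
  sc <- data.frame(
    participant_id = c("a", "a", "b"), age_group = c("young", "young", "old"),
    target = c("plant", "plant", "ball"), error = c(4, 6, 10),
    bias_two_wall = c(1, 1.2, 0.9), bias_nearest_wall = c(1, 1.1, 0.8),
    bpi_median = c(1, 1.1, 1.05), bpi_mean = c(1, 1.12, 1.06),
    outlier = FALSE, stringsAsFactors = FALSE)
  su <- participant_summary(sc)
  a_plant <- su[su$participant_id == "a" & su$target == "plant", ]
  expect_equal(a_plant$error_mean, 5)
  expect_equal(a_plant$error_median, 5)
  expect_equal(a_plant$bias_two_wall_mean, 1.1)
  b_all <- su[su$participant_id == "b" & su$target == "all", ]
  expect_equal(b_all$error_mean, 10)
  expect_equal(b_all$n_trials, 1)
})

test_that("metric correlations behave at the extremes and flag degeneracy", {
  d <- data.frame(g = rep("young", 10), x = 1:10, y = 1:10)
  r1 <- metric_correlation(d, "x", "y", "g")
  expect_equal(r1$r, 1, tolerance = 1e-12)
  set.seed(55)
  d2 <- data.frame(g = "all", x = rnorm(1000), y = rnorm(1000))
  r2 <- metric_correlation(d2, "x", "y", "g")
  expect_lt(abs(r2$r), 0.1)
  # oracle agreement
  o <- oracle_pearson(d2$x, d2$y)
  expect_equal(r2$r, o$r, tolerance = 1e-10)
  expect_equal(r2$p, o$p, tolerance = 1e-10)
  d3 <- data.frame(g = "z", x = rep(1, 5), y = rnorm(5))
  r3 <- metric_correlation(d3, "x", "y", "g")
  expect_true(is.na(r3$r))
  expect_equal(r3$note, "zero variance")
})
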