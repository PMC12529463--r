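test_that("one-sample tests match hand arithmetic and the oracle", {
  r1 <- suppressWarnings(one_sample_test(c(-1, 0, 1)))
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 1)
  r2 <- suppressWarnings(one_sample_test(c(-1, -2, -3)))
  expect_equal(r2$t, -2 / (1 / sqrt(3)), tolerance = 1e-4)  # -3.464
  set.seed(3)
  x <- rnorm(12, 0.4)
  r3 <- suppressWarnings(one_sample_test(x))
  o <- oracle_t_test(x)
  expect_equal(r3$t, o$t, tolerance = 1e-10)
  expect_equal(r3$p, o$p, tolerance = 1e-10)
  expect_error(one_sample_test(rep(2, 5)), "zero variance")
  expect_error(one_sample_test(c(1, 2)), "at least 3")
})

test_that("the one-sample test warns when normality looks doubtful", {
  set.seed(13)
  skewed <- rexp(40)^3
  expect_warning(one_sample_test(skewed), "normality")
})

test_that("covariate regression recovers exact relations and flags failures", {
  d <- data.frame(y = 2 * (1:20), x = 1:20)
  cf <- suppressWarnings(covariate_regression(d, "y", "x"))
  expect_equal(cf$estimate[cf$term == "x"], 2, tolerance = 1e-10)
  expect_lt(cf$p[cf$term == "x"], 1e-12)
  set.seed(23)
  d2 <- data.frame(y = rnorm(30), a = rnorm(30), b = rnorm(30))
  cf2 <- covariate_regression(d2, "y", c("a", "b"))
  o <- oracle_ols(cbind(1, d2$a, d2$b), d2$y)
  expect_equal(cf2$estimate, unname(o$beta), tolerance = 1e-10)
  expect_equal(cf2$se, unname(o$se), tolerance = 1e-10)
  expect_equal(cf2$p, unname(o$p), tolerance = 1e-10)
  d2$c <- d2$a
  expect_error(covariate_regression(d2, "y", c("a", "c")), "collinearity")
  expect_error(covariate_regression(d2[1:3, ], "y", c("a", "b")),
               "underdetermined")
})

test_that("the Levene test matches the deviation-ANOVA oracle", {
  x <- c(1, 2, 3, 4, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r0 <- variance_equality_test(c(x[1:3], x[1:3]), g)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:10) {
    v <- rnorm(14, sd = sample(1:3, 1))
    gg <- rep(c("a", "b"), each = 7)
    r <- variance_equality_test(v, gg)
    o <- oracle_levene(v, gg)
    expect_equal(r$F, o$F, tolerance = 1e-8)
    expect_equal(r$p, o$p, tolerance = 1e-8)
    expect_equal(r$df1, o$df1)
    expect_equal(r$df2, o$df2)
  }
  expect_error(variance_equality_test(rep(c(1, 2), each = 5),
                                      rep(c("a", "b"), each = 5)),
               "degenerate")
})

test_that("Levene detects the group variance difference at realistic scale", {
  # SDs of 0.002 vs 0.005 at n = 20/21, as seen for navigation-index spread
  set.seed(43)
  p_vals <- vapply(1:200, function(i) {
    v <- c(rnorm(20, 1, 0.002), rnorm(21, 1, 0.005))
    g <- c(rep("young", 20), rep("old", 21))
    variance_equality_test(v, g)$p
  }, numeric(1))
  expect_lt(median(p_vals), 0.05)
})

test_that("the median split assigns subgroups by the stated tie rule", {
  tab <- data.frame(participant_id = letters[1:6], error_mean = 1:6,
                    bias = c(1, 1.1, 1.2, 1.5, 1.6, 1.7))
  ms <- median_split_compare(tab, "error_mean", "bias")
  expect_equal(ms$assignment$subgroup,
               c(rep("high_performing", 3), rep("low_performing", 3)))
  o <- oracle_t_test2(tab$bias[4:6], tab$bias[1:3])
  expect_equal(ms$comparison$t, o$t, tolerance = 1e-10)
  expect_equal(ms$comparison$p, o$p, tolerance = 1e-10)
  # odd n: the middle participant (at the median) joins the low-error group
  tab7 <- data.frame(participant_id = letters[1:7], error_mean = 1:7,
                     bias = rnorm(7))
  ms7 <- median_split_compare(tab7, "error_mean", "bias")
  expect_equal(sum(ms7$assignment$subgroup == "high_performing"), 4)
  expect_equal(ms7$assignment$subgroup[4], "high_performing")
  expect_error(median_split_compare(tab[1:5, ], "error_mean", "bias"),
               "at least 6")
  tabc <- tab; tabc$error_mean <- 2
  expect_error(median_split_compare(tabc, "error_mean", "bias"), "constant")
})

test_that("sum coding halves a pure group offset in the mixed model", {
  set.seed(53)
  d <- expand.grid(participant_id = sprintf("p%02d", 1:12),
                   target = c("trash_bin", "plant", "ball"),
                   rep = 1:4, stringsAsFactors = FALSE)
  d$age_group <- ifelse(as.integer(sub("p", "", d$participant_id)) <= 6,
                        "young", "old")
  delta <- 3
  d$error <- 10 + delta * (d$age_group == "old") + rnorm(nrow(d), 0, 1e-6)
  fit <- suppressWarnings(suppressMessages(mixed_model_fit(d, "error")))
  fx <- fit$fixed_effects
  b_age <- fx$estimate[fx$term == "age_group1"]
  expect_equal(abs(b_age), delta / 2, tolerance = 1e-4)
  # no target effect was generated
  b_t <- fx$estimate[grepl("^target", fx$term) & !grepl(":", fx$term)]
  expect_true(all(abs(b_t) < 1e-3))
})

test_that("successive-difference contrasts pick up a target distance gradient", {
  set.seed(63)
  d <- expand.grid(participant_id = sprintf("p%02d", 1:16),
                   target = c("trash_bin", "plant", "ball"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$age_group <- ifelse(as.integer(sub("p", "", d$participant_id)) <= 8,
                        "young", "old")
  dist_sum <- c(trash_bin = 49, plant = 96, ball = 102)
  d$error <- 3 + 0.05 * dist_sum[d$target] + rnorm(nrow(d), 0, 1)
  fit <- suppressWarnings(suppressMessages(mixed_model_fit(d, "error")))
  fx <- fit$fixed_effects
  b21 <- fx[fx$term == "target2-1", ]
  expect_gt(b21$estimate, 0)       # plant minus trash bin
  expect_lt(b21$p, 0.01)
  expect_equal(b21$estimate, 0.05 * (96 - 49), tolerance = 0.25)
})

test_that("a singular random-slope fit falls back to a random intercept", {
  set.seed(73)
  d <- expand.grid(participant_id = sprintf("p%02d", 1:6),
                   target = c("trash_bin", "plant", "ball"),
                   rep = 1:2, stringsAsFactors = FALSE)
  d$age_group <- ifelse(as.integer(sub("p", "", d$participant_id)) <= 3,
                        "young", "old")
  d$error <- rnorm(nrow(d))  # no participant structure at all
  fit <- suppressWarnings(suppressMessages(mixed_model_fit(d, "error")))
  if (fit$singular) {
    expect_match(fit$random_structure, "fallback")
  } else {
    expect_match(fit$random_structure, "slope")
  }
  expect_true(all(is.finite(fit$fixed_effects$estimate)))
})
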