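#' One-sample t-test with normality precheck
#'
#' Two-sided one-sample t-test against a null value, with a Shapiro-Wilk
#' normality check reported alongside (and a warning when the normality
#' assumption looks doubtful, p <= 0.05).
#'
#' @param values Numeric sample (n >= 3, non-zero variance).
#' @param null Null-hypothesis mean (default 0).
#' @return List with `mean`, `t`, `df`, `p`, `shapiro_p`, `n`.
#' @export
one_sample_test <- function(values, null = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance sample", call. = FALSE)
  tt <- stats::t.test(values, mu = null)
  sw <- stats::shapiro.test(values)
  if (sw$p.value <= 0.05) {
    warning(sprintf("Shapiro-Wilk p = %.3g: normality assumption doubtful",
                    sw$p.value), call. = FALSE)
  }
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       shapiro_p = sw$p.value, n = length(values))
}

#' Covariate regression
#'
#' Ordinary least-squares regression of a response on a set of predictors
#' (raw, unstandardized), returning the per-predictor coefficient table.
#' Used both for the group comparison of modulator betas (with motion and
#' tSNR covariates) and for the brain-behavior models in older adults
#' (bias, BPI, age, screening score).
#'
#' @param table Data frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return Data frame with `term`, `estimate`, `se`, `t`, `p`.
#' @export
covariate_regression <- function(table, response, predictors) {
  stopifnot(all(c(response, predictors) %in% names(table)))
  if (nrow(table) <= length(predictors) + 1L) {
    stop("model is underdetermined: n must exceed predictors + 1", call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = table)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("exact collinearity among predictors: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Levene's test for equality of variances
#'
#' Classic (mean-centered) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group mean.
#'
#' @param values Numeric vector.
#' @param group Grouping factor (two or more groups, each n >= 3).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
variance_equality_test <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2)
  if (any(table(group) < 3)) stop("each group needs n >= 3", call. = FALSE)
  dev <- abs(values - stats::ave(values, group))
  if (all(dev < 1e-12)) {
    stop("all within-group deviations are zero; variance test degenerate",
         call. = FALSE)
  }
  a <- stats::anova(stats::lm(dev ~ group))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1])
}

#' Median-split comparison of high- vs low-performing participants
#'
#' Splits a participant table into high- and low-performing subgroups at
#' the median of the split metric (mean Euclidean error by default: at or
#' below the median = high-performing / low-error) and compares each
#' outcome metric between subgroups with a pooled-variance two-sample
#' t-test. Participants exactly at the median join the low-error
#' (high-performing) subgroup, which also absorbs the odd middle
#' participant.
#'
#' @param table Per-participant data frame.
#' @param split_metric Column used for the split.
#' @param outcomes Character vector of outcome columns to compare.
#' @return List with `assignment` (data frame of participant subgroups) and
#'   `comparison` (per-outcome means, t, df, p).
#' @export
median_split_compare <- function(table, split_metric = "error_mean",
                                 outcomes) {
  stopifnot(split_metric %in% names(table), all(outcomes %in% names(table)))
  if (nrow(table) < 6L) stop("need at least 6 participants", call. = FALSE)
  v <- table[[split_metric]]
  if (stats::sd(v) == 0) {
    stop("split metric is constant; median split undefined", call. = FALSE)
  }
  med <- stats::median(v)
  subgroup <- ifelse(v <= med, "high_performing", "low_performing")
  rows <- lapply(outcomes, function(m) {
    hi <- table[[m]][subgroup == "high_performing"]
    lo <- table[[m]][subgroup == "low_performing"]
    tt <- stats::t.test(lo, hi, var.equal = TRUE)
    data.frame(outcome = m, mean_low_performing = mean(lo),
               mean_high_performing = mean(hi),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  list(assignment = data.frame(participant_id = table$participant_id %||%
                                 seq_len(nrow(table)),
                               subgroup = subgroup, stringsAsFactors = FALSE),
       comparison = do.call(rbind, rows))
}

#' Linear mixed-effects model for trial-level metrics
#'
#' Fits the trial-level model used for all behavioral metrics: fixed
#' effects of age group (sum-coded), target location (successive-difference
#' contrasts: trash bin vs plant, then plant vs ball) and their
#' interaction, with a by-participant random intercept and random slope for
#' target location. Estimation is delegated to `lmerTest::lmer`
#' (Satterthwaite degrees of freedom); when the random-slope fit is
#' singular the model falls back to a random intercept only, flagged in the
#' output.
#'
#' @param trials Trial-level data frame with `participant_id`, `age_group`,
#'   `target` and the response column.
#' @param response Response column name (e.g. `"error"`).
#' @param target_levels Target factor order; successive-difference
#'   contrasts compare consecutive levels.
#' @return List with `fixed_effects` (term/estimate/se/df/t/p), `singular`
#'   (logical), `random_structure`, and the fitted `model`.
#' @export
mixed_model_fit <- function(trials, response,
                            target_levels = c("trash_bin", "plant", "ball")) {
  stopifnot(all(c("participant_id", "age_group", "target", response) %in%
                  names(trials)))
  d <- trials
  d$age_group <- factor(d$age_group, levels = c("young", "old"))
  if (nlevels(droplevels(d$age_group)) < 2L) {
    stop("need both age groups", call. = FALSE)
  }
  d$target <- factor(d$target, levels = target_levels)
  stats::contrasts(d$age_group) <- stats::contr.sum(2)
  stats::contrasts(d$target) <- MASS::contr.sdif(length(target_levels))
  d$.y <- d[[response]]

  fml <- stats::as.formula(".y ~ age_group * target + (1 + target | participant_id)")
  fit <- suppressMessages(lmerTest::lmer(fml, data = d,
                                         control = lme4::lmerControl(calc.derivs = FALSE)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  random_structure <- "intercept + target slope"
  if (singular) {
    warning("random-slope fit singular; falling back to random intercept only",
            call. = FALSE)
    fml <- stats::as.formula(".y ~ age_group * target + (1 | participant_id)")
    fit <- suppressMessages(lmerTest::lmer(fml, data = d))
    random_structure <- "intercept only (fallback)"
  }
  cf <- stats::coef(summary(fit))
  list(fixed_effects = data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                                  se = cf[, "Std. Error"], df = cf[, "df"],
                                  t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                                  row.names = NULL, stringsAsFactors = FALSE),
       singular = singular, random_structure = random_structure, model = fit)
}
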