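#' Parametric-modulator recovery experiment
#'
#' Simulates `n_runs` independent navigation sessions and BOLD runs at a
#' known modulator effect and re-estimates the effect with the full
#' first-level pipeline (aCompCor from the run's own noise voxels, design
#' build, OLS fit). Used to verify that the estimator recovers the
#' generating effect at the calibrated signal-to-noise level.
#'
#' @param n_runs Number of independent runs.
#' @param truth A [bold_truth()] (its `beta_pmod` is the generating value).
#' @param cfg A [scan_config()].
#' @param params [agent_params()] controlling the navigation style.
#' @param arena An [arena()].
#' @param rng_seed Master seed.
#' @return Data frame with one row per run: `beta_true`, `beta_hat`.
#' @export
pmod_recovery <- function(n_runs = 200, truth = bold_truth(),
                          cfg = scan_config(),
                          params = default_group_params()$old,
                          arena = boundnav::arena(), rng_seed = 1L) {
  beta_hat <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    s <- simulate_session(cfg$run_duration, params, arena,
                          rng_seed = derive_seed(rng_seed, i, 10L))
    run <- simulate_bold_run(s, cfg, truth,
                             rng_seed = derive_seed(rng_seed, i, 11L), arena)
    beta_hat[i] <- fit_bold_run(run)$beta_pmod
  }
  data.frame(beta_true = truth$beta_pmod, beta_hat = beta_hat)
}

#' Null calibration of the group-level one-sample test
#'
#' Estimates the empirical type-I error of the one-sample t-test applied to
#' per-participant modulator estimates when the true modulator effect is
#' zero. A fixed pool of `n_participants` sessions and their first-level
#' designs is built once; each replication redraws every participant's
#' AR(1) scanner noise and refits the GLM. Holding the deterministic run
#' structure fixed is exact here: every deterministic signal component
#' (condition response, motion, physiological leakage, drift) lies in the
#' design span, so it contributes exactly zero to the modulator estimate
#' and only the resampled noise propagates into the group test.
#'
#' @param n_sims Number of null replications.
#' @param n_participants Participants (runs) per replication.
#' @param truth A [bold_truth()]; its `beta_pmod` is forced to zero.
#' @param cfg A [scan_config()].
#' @param params [agent_params()] for the sessions.
#' @param arena An [arena()].
#' @param rng_seed Master seed.
#' @param alpha Nominal test level.
#' @return List with `rejection_rate`, `p_values`, `n_sims`,
#'   `n_participants`.
#' @export
pmod_null_calibration <- function(n_sims = 500, n_participants = 15,
                                  truth = bold_truth(), cfg = scan_config(),
                                  params = default_group_params()$old,
                                  arena = boundnav::arena(), rng_seed = 1L,
                                  alpha = 0.05) {
  truth$beta_pmod <- 0
  noiseless <- truth
  noiseless$noise_sd <- 0
  qrs <- vector("list", n_participants)
  y0 <- vector("list", n_participants)
  n <- cfg$n_volumes
  for (i in seq_len(n_participants)) {
    s <- simulate_session(cfg$run_duration, params, arena,
                          rng_seed = derive_seed(rng_seed, i, 20L))
    run <- simulate_bold_run(s, cfg, noiseless,
                             rng_seed = derive_seed(rng_seed, i, 21L), arena)
    comps <- compcor_components(run$noise_voxels, cfg$n_compcor)
    X <- build_design(run$events, run$pmod, run$motion, comps, cfg)
    qrs[[i]] <- qr(unclass(X)[, , drop = FALSE])
    y0[[i]] <- run$roi
  }
  p_values <- local_seed(derive_seed(rng_seed, 0L, 22L), {
    vapply(seq_len(n_sims), function(s) {
      betas <- vapply(seq_len(n_participants), function(i) {
        y <- y0[[i]] + ar1_noise(n, truth$ar1_phi, truth$noise_sd)
        unname(qr.coef(qrs[[i]], y)["pmod"])
      }, numeric(1))
      stats::t.test(betas, mu = 0)$p.value
    }, numeric(1))
  })
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       n_sims = n_sims, n_participants = n_participants)
}
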