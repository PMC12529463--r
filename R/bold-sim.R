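#' Ground truth for a simulated BOLD run
#'
#' The generating parameters recorded alongside every simulated run so that
#' recovery tests can compare estimates against truth. The default
#' modulator effect (-0.004 signal units per vm) matches the scale of
#' boundary-distance modulation observed in older adults' entorhinal
#' cortex.
#'
#' @param beta_condition Amplitude of the translation-condition response.
#' @param beta_pmod Boundary-distance modulation, signal units per vm.
#' @param ar1_phi AR(1) coefficient of the scanner noise, `|phi| < 1`.
#' @param noise_sd Marginal SD of the AR(1) noise.
#' @param baseline Mean signal level (sets the tSNR scale).
#' @param motion_amp Step SD of the motion random walks (mm / deg).
#' @param motion_coupling SD of the per-parameter motion-to-signal leakage.
#' @param physio_amp Amplitude of physiological signal leakage into the ROI.
#' @param drift_amp Amplitude of low-frequency drift.
#' @return A list of class `bold_truth`.
#' @export
bold_truth <- function(beta_condition = 1, beta_pmod = -0.004,
                       ar1_phi = 0.3, noise_sd = 1, baseline = 100,
                       motion_amp = 0.02, motion_coupling = 0.2,
                       physio_amp = 0.5, drift_amp = 2) {
  stopifnot(abs(ar1_phi) < 1, noise_sd >= 0)
  structure(list(beta_condition = beta_condition, beta_pmod = beta_pmod,
                 ar1_phi = ar1_phi, noise_sd = noise_sd, baseline = baseline,
                 motion_amp = motion_amp, motion_coupling = motion_coupling,
                 physio_amp = physio_amp, drift_amp = drift_amp),
            class = "bold_truth")
}

# Marginal-variance-preserving AR(1) noise.
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

#' Simulate an ROI BOLD run from a navigation trajectory
#'
#' Generative twin of the first-level model: the ROI signal is the
#' HRF-convolved translation regressor times `beta_condition`, plus the
#' convolved mean-centered boundary-distance modulator times `beta_pmod`,
#' plus motion leakage, physiological noise shared with a bank of synthetic
#' noise-mask voxels (so aCompCor can be exercised on the same run), a
#' low-frequency drift lying in the span of the DCT set, and AR(1) scanner
#' noise. The generating truth is returned with the data.
#'
#' @param trajectory A `trajectory` spanning the run (e.g. from
#'   [simulate_session()]).
#' @param cfg A [scan_config()].
#' @param truth A [bold_truth()].
#' @param rng_seed Integer seed for noise and nuisance draws.
#' @param arena An [arena()].
#' @param n_noise_voxels Number of synthetic noise-mask voxels.
#' @return A list of class `bold_run`: `roi` (signal vector), `motion`
#'   (volumes x 6), `noise_voxels` (volumes x voxels), `events`, `pmod`,
#'   `truth`, `cfg`.
#' @export
simulate_bold_run <- function(trajectory, cfg = scan_config(),
                              truth = bold_truth(), rng_seed = 1L,
                              arena = boundnav::arena(),
                              n_noise_voxels = 40) {
  n <- cfg$n_volumes
  if (n < 2L) stop("run must contain at least 2 TRs", call. = FALSE)
  events <- translation_tr_events(trajectory, cfg)
  if (nrow(events) == 0L) stop("trajectory contains no translation events", call. = FALSE)
  pmod <- pmod_series(trajectory, events, arena, cfg)

  cond_stick <- numeric(n); cond_stick[events$volume] <- 1
  pmod_stick <- numeric(n); pmod_stick[events$volume] <- pmod - mean(pmod)
  cond_reg <- hrf_convolve(cond_stick, cfg)
  pmod_reg <- hrf_convolve(pmod_stick, cfg)

  local_seed(rng_seed, {
    # motion: slow random walks, translations (mm) and rotations (deg)
    motion <- vapply(1:6, function(j) cumsum(stats::rnorm(n, 0, truth$motion_amp)),
                     numeric(n))
    colnames(motion) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")
    motion_w <- stats::rnorm(6, 0, truth$motion_coupling)

    # two physiological source signals (aliased respiratory/cardiac bands)
    tt <- (seq_len(n) - 1) * cfg$tr
    physio <- cbind(sin(2 * pi * 0.031 * tt + stats::runif(1, 0, 2 * pi)),
                    sin(2 * pi * 0.083 * tt + stats::runif(1, 0, 2 * pi)))
    physio_w <- stats::rnorm(2, 0, truth$physio_amp)

    # drift built from the leading DCT columns, hence removable exactly
    dct <- dct_highpass_set(n, cfg)
    n_drift <- min(3L, ncol(dct))
    drift <- drop(dct[, seq_len(n_drift), drop = FALSE] %*%
                    stats::rnorm(n_drift, 0, truth$drift_amp))

    roi <- truth$baseline +
      cond_reg * truth$beta_condition +
      pmod_reg * truth$beta_pmod +
      drop(motion %*% motion_w) +
      drop(physio %*% physio_w) +
      drift +
      ar1_noise(n, truth$ar1_phi, truth$noise_sd)

    # noise-mask voxels: random mixtures of the physiological sources plus
    # voxel-specific white noise
    mix <- matrix(stats::rnorm(2 * n_noise_voxels, 0, 1), 2, n_noise_voxels)
    vox_noise_sd <- if (truth$noise_sd == 0) 0 else 0.3
    noise_voxels <- physio %*% mix +
      matrix(stats::rnorm(n * n_noise_voxels, 0, vox_noise_sd), n, n_noise_voxels)

    structure(list(roi = roi, motion = motion, noise_voxels = noise_voxels,
                   events = events, pmod = pmod, truth = truth, cfg = cfg),
              class = "bold_run")
  })
}

#' Fit the first-level model to a simulated run
#'
#' Convenience wrapper: estimates aCompCor components from the run's
#' noise-mask voxels, assembles the full design (condition, modulator,
#' motion, components, drift, intercept) and fits the GLM to the ROI
#' series.
#'
#' @param run A `bold_run`.
#' @return A `glm_result` (see [fit_glm()]); the design is attached as
#'   attribute `design`.
#' @export
fit_bold_run <- function(run) {
  comps <- compcor_components(run$noise_voxels, run$cfg$n_compcor)
  X <- build_design(run$events, run$pmod, run$motion, comps, run$cfg)
  res <- fit_glm(run$roi, X)
  attr(res, "design") <- X
  res
}

#' Write a run's noise-mask voxels as a small 4D NIfTI volume
#'
#' Arranges the synthetic noise voxels on a tiny grid and writes a 4D image
#' plus a binary mask, for exercising NIfTI-based aCompCor input (requires
#' RNifti).
#'
#' @param run A `bold_run`.
#' @param path Output path for the 4D image (`.nii` / `.nii.gz`).
#' @param mask_path Output path for the mask image.
#' @return Invisibly, the paths written.
#' @export
write_noise_volume <- function(run, path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI output requires the RNifti package", call. = FALSE)
  }
  v <- ncol(run$noise_voxels)
  n <- nrow(run$noise_voxels)
  side <- ceiling(sqrt(v))
  arr <- array(0, dim = c(side, side, 1, n))
  mask <- array(0L, dim = c(side, side, 1))
  for (j in seq_len(v)) {
    i1 <- ((j - 1) %% side) + 1
    i2 <- ((j - 1) %/% side) + 1
    arr[i1, i2, 1, ] <- run$noise_voxels[, j]
    mask[i1, i2, 1] <- 1L
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  invisible(c(path, mask_path))
}
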