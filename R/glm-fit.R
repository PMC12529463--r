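#' Fit the first-level GLM to an ROI time series
#'
#' Ordinary least squares on the full design. Estimation deliberately uses
#' OLS without autocorrelation prewhitening; simulated noise retains AR(1)
#' structure so that recovery tests reflect this choice honestly (the
#' group-level one-sample test across runs remains calibrated because
#' between-run variability is estimated empirically).
#'
#' @param y Numeric ROI time series, one value per volume.
#' @param design A `design_matrix` from [build_design()], or any full-rank
#'   numeric matrix with named columns.
#' @return A list of class `glm_result`: `betas` (named), `beta_pmod`,
#'   `se` (named standard errors), `sigma2` (residual variance), `df`,
#'   `fitted`, `residuals`.
#' @export
fit_glm <- function(y, design) {
  X <- unclass(design)
  attr(X, "events") <- attr(X, "pmod_centered") <- attr(X, "cfg") <- NULL
  if (length(y) != nrow(X)) {
    stop(sprintf("series length (%d) != design rows (%d)", length(y), nrow(X)),
         call. = FALSE)
  }
  if (any(!is.finite(y))) stop("non-finite values in ROI series", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- length(y) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(X)
  structure(list(betas = beta,
                 beta_pmod = unname(beta["pmod"]),
                 se = se, sigma2 = sigma2, df = df,
                 fitted = fitted, residuals = resid),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d regressors, df = %d, beta_pmod = %.5g\n",
              length(x$betas), x$df, x$beta_pmod))
  invisible(x)
}

#' aCompCor noise components
#'
#' Principal components of the voxel-demeaned noise-mask (white matter +
#' CSF) time series, ordered by explained variance, unit-normalized and
#' mutually orthogonal. The leading components capture physiological
#' signals shared across noise voxels and enter the design as nuisance
#' regressors. Instead of a matrix, NIfTI file paths for a 4D series and a
#' binary mask may be given (requires the RNifti package).
#'
#' @param noise_series `n_volumes x n_voxels` numeric matrix of noise-mask
#'   voxel time series, or the path to a 4D NIfTI file.
#' @param n_components Number of components to retain (default 5).
#' @param mask Optional path to a mask NIfTI when `noise_series` is a file.
#' @return `n_volumes x n_components` matrix with attribute
#'   `explained_variance` (fractions, non-increasing).
#' @export
compcor_components <- function(noise_series, n_components = 5, mask = NULL) {
  if (is.character(noise_series)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI input requires the RNifti package", call. = FALSE)
    }
    vol <- RNifti::readNifti(noise_series)
    dm <- dim(vol)
    stopifnot(length(dm) == 4L)
    vox <- matrix(vol, ncol = dm[4])  # voxels x time
    if (!is.null(mask)) {
      m <- as.logical(RNifti::readNifti(mask) > 0)
      vox <- vox[m, , drop = FALSE]
    }
    noise_series <- t(vox)
  }
  noise_series <- as.matrix(noise_series)
  if (ncol(noise_series) < n_components) {
    stop(sprintf("need at least %d noise voxels, got %d",
                 n_components, ncol(noise_series)), call. = FALSE)
  }
  centered <- scale(noise_series, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    stop("noise-mask series has zero variance", call. = FALSE)
  }
  sv <- svd(centered, nu = n_components, nv = 0)
  comps <- sv$u[, seq_len(n_components), drop = FALSE]
  colnames(comps) <- sprintf("compcor_%d", seq_len(n_components))
  ev <- sv$d^2 / sum(sv$d^2)
  attr(comps, "explained_variance") <- ev[seq_len(n_components)]
  comps
}

#' ROI and motion quality metrics
#'
#' Temporal signal-to-noise ratio (temporal mean divided by temporal SD of
#' the ROI series) and per-volume motion summaries: the framewise absolute
#' change summed across the three translation axes (and separately across
#' yaw/pitch/roll), averaged over the run.
#'
#' @param y Numeric ROI time series (length >= 2).
#' @param motion `n_volumes x 6` matrix or data frame with translation
#'   columns first (x, y, z) then rotations (yaw, pitch, roll).
#' @return List with `tsnr` (NA with a note if the temporal SD is zero),
#'   `mean_linear_displacement`, `mean_angular_displacement`.
#' @export
quality_metrics <- function(y, motion) {
  stopifnot(length(y) >= 2)
  s <- stats::sd(y)
  tsnr <- if (s == 0) NA_real_ else mean(y) / s
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) >= 6, nrow(motion) == length(y))
  d <- abs(apply(motion, 2, diff))
  lin <- mean(rowSums(d[, 1:3, drop = FALSE]))
  ang <- mean(rowSums(d[, 4:6, drop = FALSE]))
  list(tsnr = tsnr,
       tsnr_note = if (s == 0) "zero temporal SD; tSNR undefined" else "",
       mean_linear_displacement = lin,
       mean_angular_displacement = ang)
}

#' Truncate a run to a fraction of its volumes
#'
#' Removes the final `floor(fraction * n_volumes)` volumes, together with
#' any translation events falling inside them, from a simulated run. Used
#' for the control analysis matching run lengths across groups (young runs
#' truncated by 19.84% to match old runs). The design must be rebuilt from
#' the truncated pieces.
#'
#' @param run A `bold_run` from [simulate_bold_run()], or a list with
#'   elements `roi`, `motion`, `noise_voxels`, `events`, `pmod`, `cfg`.
#' @param fraction Fraction of volumes to drop from the end, in `[0, 1)`.
#' @return The run with volumes and events truncated; `cfg` is updated to
#'   the shortened duration.
#' @export
truncate_run <- function(run, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(run$roi)
  n_keep <- n - floor(fraction * n)
  keep_ev <- run$events$volume <= n_keep
  if (sum(keep_ev) < 2L) {
    stop("truncation would leave fewer than 2 translation events", call. = FALSE)
  }
  run$roi <- run$roi[seq_len(n_keep)]
  if (!is.null(run$motion)) run$motion <- run$motion[seq_len(n_keep), , drop = FALSE]
  if (!is.null(run$noise_voxels)) {
    run$noise_voxels <- run$noise_voxels[seq_len(n_keep), , drop = FALSE]
  }
  run$pmod <- run$pmod[keep_ev]
  run$events <- run$events[keep_ev, , drop = FALSE]
  run$cfg <- scan_config(tr = run$cfg$tr, run_duration = n_keep * run$cfg$tr,
                         highpass_cutoff = run$cfg$highpass_cutoff,
                         n_compcor = run$cfg$n_compcor)
  run
}
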