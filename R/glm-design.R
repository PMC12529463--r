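#' Scan configuration
#'
#' Acquisition and first-level model settings: repetition time (TR) 1.5 s,
#' run duration 16 min, a 128-s high-pass cutoff for drift removal, and
#' five aCompCor components.
#'
#' @param tr Repetition time in seconds.
#' @param run_duration Run length in seconds; must be a multiple of `tr`.
#' @param highpass_cutoff High-pass period cutoff in seconds; must exceed
#'   `2 * tr`.
#' @param n_compcor Number of aCompCor components in the design.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(tr = 1.5, run_duration = 960,
                        highpass_cutoff = 128, n_compcor = 5) {
  stopifnot(tr > 0, run_duration > 0, n_compcor >= 0)
  if (abs(run_duration / tr - round(run_duration / tr)) > 1e-8) {
    stop("`run_duration` must be a multiple of `tr`", call. = FALSE)
  }
  if (highpass_cutoff <= 2 * tr) {
    stop("`highpass_cutoff` must exceed 2 * tr", call. = FALSE)
  }
  structure(list(tr = tr, run_duration = run_duration,
                 highpass_cutoff = highpass_cutoff,
                 n_compcor = as.integer(n_compcor),
                 n_volumes = as.integer(round(run_duration / tr))),
            class = "scan_config")
}

# Sampling interval of a trajectory, inferred from its time grid.
traj_dt <- function(trajectory) {
  dts <- diff(trajectory$t)
  stats::median(dts)
}

#' Translation-event TRs of a run
#'
#' Assigns trajectory samples to half-open TR windows
#' `[(k - 1) * tr, k * tr)` and marks a TR as a translation event if any
#' translation sample falls inside its window. Each event is modeled
#' downstream with a fixed duration of one TR. The fraction of the window
#' spent translating is recorded so stricter event rules can be evaluated.
#'
#' @param trajectory A `trajectory` data frame spanning the run.
#' @param cfg A [scan_config()].
#' @return Data frame with columns `volume` (1-based TR index) and
#'   `fraction` (translated fraction of that window), one row per event TR.
#' @export
translation_tr_events <- function(trajectory, cfg = scan_config()) {
  if (max(trajectory$t) < cfg$run_duration - cfg$tr) {
    stop(sprintf("trajectory (%.1f s) does not span the run (%.1f s)",
                 max(trajectory$t), cfg$run_duration), call. = FALSE)
  }
  dt <- traj_dt(trajectory)
  in_run <- trajectory$t < cfg$run_duration - 1e-9
  tt <- trajectory$t[in_run]
  moving <- trajectory$moving[in_run]
  vol <- floor(tt / cfg$tr + 1e-9) + 1L
  trans <- moving == "translation"
  if (!any(trans)) {
    return(data.frame(volume = integer(0), fraction = numeric(0)))
  }
  counts <- tapply(trans, vol, sum)
  counts <- counts[counts > 0]
  data.frame(volume = as.integer(names(counts)),
             fraction = as.numeric(counts) * dt / cfg$tr)
}

#' Boundary-distance parametric modulator per event TR
#'
#' For each translation-event TR, the mean distance to the nearer x-wall
#' and the mean distance to the nearer y-wall are computed across all
#' samples of the full TR window (moving or not, since movement is
#' continuous within the window), and the two per-axis means are summed.
#'
#' @param trajectory A `trajectory` data frame spanning the run.
#' @param events Event table from [translation_tr_events()].
#' @param arena An [arena()].
#' @param cfg A [scan_config()].
#' @return Numeric vector (one value per event TR) in
#'   `[0, side_length]` vm.
#' @export
pmod_series <- function(trajectory, events, arena = boundnav::arena(),
                        cfg = scan_config()) {
  if (nrow(events) == 0L) stop("no translation events", call. = FALSE)
  vol <- floor(trajectory$t / cfg$tr + 1e-9) + 1L
  dx <- axis_wall_distance(cbind(trajectory$x, trajectory$y), arena, "x")
  dy <- axis_wall_distance(cbind(trajectory$x, trajectory$y), arena, "y")
  vapply(events$volume, function(k) {
    sel <- vol == k
    if (!any(sel)) stop(sprintf("event TR %d has no trajectory samples", k),
                        call. = FALSE)
    mean(dx[sel]) + mean(dy[sel])
  }, numeric(1))
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response (response peak 6 s, undershoot
#' peak 16 s, peak-to-undershoot ratio 6, length 32 s), sampled on the
#' volume grid and scaled to unit peak.
#'
#' @param tr Sampling interval in seconds.
#' @param length_s Kernel length in seconds.
#' @return Numeric vector of kernel samples at `0, tr, 2 tr, ...`.
#' @export
canonical_hrf <- function(tr = 1.5, length_s = 32) {
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve a volume-gridded series with the canonical HRF
#'
#' Linear, causal convolution of a (possibly modulated) stick series with
#' the double-gamma kernel, truncated to the run length.
#'
#' @param series Numeric vector on the volume grid.
#' @param cfg A [scan_config()] (supplies the TR).
#' @return Numeric vector of the same length as `series`.
#' @export
hrf_convolve <- function(series, cfg = scan_config()) {
  h <- canonical_hrf(cfg$tr)
  n <- length(series)
  out <- stats::convolve(series, rev(h), type = "open")
  out[seq_len(n)]
}

#' Discrete-cosine high-pass drift set
#'
#' Orthonormal DCT basis columns whose periods exceed the high-pass cutoff;
#' including them in the design removes low-frequency drift (equivalent to
#' high-pass filtering both data and model). The number of columns is
#' `floor(2 * run_duration / cutoff)`.
#'
#' @param n_volumes Number of volumes in the run.
#' @param cfg A [scan_config()].
#' @return An `n_volumes x k` matrix of orthonormal drift regressors
#'   (columns `dct_1 ... dct_k`).
#' @export
dct_highpass_set <- function(n_volumes, cfg = scan_config()) {
  if (cfg$highpass_cutoff <= 2 * cfg$tr) stop("cutoff too small", call. = FALSE)
  k <- floor(2 * n_volumes * cfg$tr / cfg$highpass_cutoff)
  n <- seq_len(n_volumes) - 1L
  basis <- vapply(seq_len(k), function(j) {
    v <- cos(pi * (2 * n + 1) * j / (2 * n_volumes))
    v * sqrt(2 / n_volumes)
  }, numeric(n_volumes))
  basis <- matrix(basis, nrow = n_volumes, ncol = k)
  colnames(basis) <- sprintf("dct_%d", seq_len(k))
  basis
}

#' Build the first-level design matrix
#'
#' Assembles the translation-condition regressor (convolved unit sticks at
#' event TRs), the boundary-distance parametric modulator (convolved sticks
#' carrying the pmod values mean-centered over event TRs, entered as a
#' first-order term without orthogonalization against the condition), the
#' six motion parameters, the aCompCor components, the DCT drift set, and
#' an intercept (last column). Nuisance and drift columns enter
#' unconvolved.
#'
#' @param events Event table from [translation_tr_events()].
#' @param pmod Numeric vector of modulator values, one per event TR.
#' @param motion `n_volumes x 6` matrix or data frame of motion parameters
#'   (translations x/y/z, rotations yaw/pitch/roll), or `NULL`.
#' @param compcor `n_volumes x k` matrix of aCompCor components, or `NULL`.
#' @param cfg A [scan_config()].
#' @return A `design_matrix`: numeric matrix with named columns and
#'   attributes `events` and `pmod_centered`.
#' @export
build_design <- function(events, pmod, motion = NULL, compcor = NULL,
                         cfg = scan_config()) {
  n <- cfg$n_volumes
  if (nrow(events) == 0L) {
    stop("cannot build a design with no translation events", call. = FALSE)
  }
  stopifnot(length(pmod) == nrow(events))
  cond_stick <- numeric(n)
  cond_stick[events$volume] <- 1
  pmod_c <- pmod - mean(pmod)
  pmod_stick <- numeric(n)
  pmod_stick[events$volume] <- pmod_c
  X <- cbind(condition = hrf_convolve(cond_stick, cfg),
             pmod = hrf_convolve(pmod_stick, cfg))
  if (max(abs(pmod_c)) < 1e-12) {
    stop("modulator is constant across events: pmod column is zero after centering and beta_pmod is inestimable",
         call. = FALSE)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n)
    if (is.null(colnames(motion))) {
      colnames(motion) <- c("tx", "ty", "tz", "yaw", "pitch", "roll")[seq_len(ncol(motion))]
    }
    X <- cbind(X, motion)
  }
  if (!is.null(compcor)) {
    compcor <- as.matrix(compcor)
    stopifnot(nrow(compcor) == n)
    if (is.null(colnames(compcor))) {
      colnames(compcor) <- sprintf("compcor_%d", seq_len(ncol(compcor)))
    }
    X <- cbind(X, compcor)
  }
  X <- cbind(X, dct_highpass_set(n, cfg), intercept = 1)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  structure(X, events = events, pmod_centered = pmod_c, cfg = cfg,
            class = c("design_matrix", class(X)))
}
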