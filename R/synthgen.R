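#' Noise and drift specification for simulated BOLD
#'
#' The generator's noise model: a positive baseline intensity, stationary
#' AR(1) Gaussian noise of standard deviation `sigma`, and slow scanner
#' drift expressed as a polynomial on time normalized to `[-1, 1]`
#' (matching the detrending basis used in preprocessing, so noise-free
#' recovery is exact). Background (out-of-mask) voxels receive small
#' independent noise rather than zeros so that masking is genuinely
#' exercised and temporal-SNR maps stay finite.
#'
#' @param baseline Mean in-brain intensity (arbitrary units, > 0). The
#'   default 100 with `sigma = 2.2` yields a temporal SNR near 45, the level
#'   this class of close-fitting receive arrays attains in vivo.
#' @param sigma Stationary noise standard deviation (>= 0).
#' @param ar1_phi AR(1) coefficient, `|phi| < 1`. The default 0.1 keeps the
#'   noise close to white: the raw-df Fisher-Z null calibration the synchrony
#'   analysis relies on is inflated by `sqrt((1 + phi^2) / (1 - phi^2))`
#'   under AR(1) noise, so strong autocorrelation would de-calibrate it (see
#'   the package vignette).
#' @param drift_coeffs Coefficients of `u, u^2, ...` (u = normalized time);
#'   relative drift, multiplying the baseline.
#' @param background_sigma SD of the independent out-of-mask noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline = 100, sigma = 2.2, ar1_phi = 0.1,
                       drift_coeffs = c(0.01, -0.005),
                       background_sigma = 1) {
  stopifnot(baseline > 0, sigma >= 0, abs(ar1_phi) < 1, background_sigma >= 0)
  structure(list(baseline = baseline, sigma = sigma, ar1_phi = ar1_phi,
                 drift_coeffs = as.numeric(drift_coeffs),
                 background_sigma = background_sigma), class = "noise_spec")
}

#' Inter-brain coupling specification
#'
#' Designates the region of interest whose voxels carry a shared band-limited
#' latent signal in both subjects (at spatially analogous indices, i.e.
#' mirrored across subjects once both are in the canonical convention), and
#' the target inter-brain Pearson correlation the coupling should induce.
#'
#' @param roi A [mask3d()] of coupled voxels.
#' @param rho Target inter-brain correlation in `[0, 1)`.
#' @param band_hz Frequency band of the shared signal; the default 0.01-0.1
#'   Hz matches the temporal filter used in resting preprocessing.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(roi, rho, band_hz = c(0.01, 0.1)) {
  stopifnot(inherits(roi, "mask3d"), rho >= 0, rho < 1,
            length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1])
  structure(list(roi = roi, rho = rho, band_hz = as.numeric(band_hz)),
            class = "coupling_spec")
}

#' Amplitude of a shared unit-variance latent inducing correlation rho
#'
#' If two voxels each observe `c * g(t) + noise` with a common unit-variance
#' latent `g` and independent noise of SD `sigma`, their correlation is
#' `c^2 / (c^2 + sigma^2)`. Solving for `c` gives
#' `c = sigma * sqrt(rho / (1 - rho))`.
#'
#' @param rho Target correlation in `[0, 1)`.
#' @param sigma Independent-noise standard deviation (> 0).
#' @return The coupling amplitude `c`.
#' @export
coupling_amplitude <- function(rho, sigma) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  stopifnot(all(sigma > 0))
  sigma * sqrt(rho / (1 - rho))
}

#' Sample a band-limited shared latent signal
#'
#' White Gaussian noise is restricted to the requested frequency band in the
#' Fourier domain and standardized to zero mean and unit variance, producing
#' the latent time course shared by coupled voxels of the two subjects.
#'
#' @param n_volumes Number of time points (>= 8).
#' @param tr_s Sampling interval in seconds.
#' @param band_hz Two frequencies `(low, high)` with `high` below Nyquist.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return Numeric vector of length `n_volumes`, mean 0, SD 1.
#' @export
sample_shared_signal <- function(n_volumes, tr_s, band_hz = c(0.01, 0.1),
                                 seed = 1) {
  stopifnot(n_volumes >= 8, tr_s > 0, length(band_hz) == 2)
  nyq <- 1 / (2 * tr_s)
  if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1] || band_hz[2] > nyq)
    stop(sprintf("band (%g, %g) Hz invalid for Nyquist %g Hz",
                 band_hz[1], band_hz[2], nyq))
  x <- with_seed(seed, stats::rnorm(n_volumes))
  freq <- seq(0, n_volumes - 1) / (n_volumes * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)  # fold to [0, Nyquist]
  keep <- freq >= band_hz[1] & freq <= band_hz[2]
  if (!any(keep)) stop("band contains no Fourier bin at this length/TR")
  xf <- stats::fft(x)
  xf[!keep] <- 0
  g <- Re(stats::fft(xf, inverse = TRUE)) / n_volumes
  as.numeric((g - mean(g)) / stats::sd(g))
}

# AR(1) noise matrix (nvox x n) with stationary SD sigma; caller seeds RNG
ar1_noise <- function(nvox, n, sigma, phi) {
  if (sigma == 0 || nvox == 0) return(matrix(0, nvox, n))
  e <- matrix(0, nvox, n)
  e[, 1] <- stats::rnorm(nvox, 0, sigma)
  if (n > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (t in 2:n) e[, t] <- phi * e[, t - 1] + stats::rnorm(nvox, 0, innov_sd)
  }
  e
}

poly_drift <- function(n, coeffs) {
  if (length(coeffs) == 0) return(rep(0, n))
  u <- seq(-1, 1, length.out = n)
  drift <- rep(0, n)
  for (k in seq_along(coeffs)) drift <- drift + coeffs[k] * u^k
  drift
}

#' Simulate a paired two-subject BOLD acquisition with known ground truth
#'
#' Generates matched runs for two subjects on a common grid. Each in-mask
#' voxel follows
#' `baseline * (1 + drift(t)) + c(v) * g(t) + beta(v) * x_task(t) + eps(v, t)`
#' where `g` is a band-limited latent shared (within a run) between
#' spatially analogous ROI voxels of the two subjects with amplitude
#' `c = coupling_amplitude(rho, sigma)`, `x_task` is the HRF-convolved
#' stimulus regressor, and `eps` is AR(1) noise, independent across voxels,
#' subjects and runs. The latent is standardized per run, so the induced
#' inter-brain correlation equals `rho` in expectation per run. Out-of-mask
#' voxels carry small independent background noise. All RNG streams are
#' derived from one master seed by subject/run labels, so results are
#' bit-reproducible.
#'
#' @param grid List with `dim` (3 integers), `voxel_size_mm`, `tr_s`.
#' @param masks List of two [mask3d()] brain masks (one per subject); a
#'   single mask is recycled for both.
#' @param coupling A [coupling_spec()] or `NULL` for uncoupled subjects.
#' @param task `NULL`, or list with `design` (a [block_design()]), `beta`
#'   (response amplitude, intensity units), optional `roi` ([mask3d()],
#'   default: coupling ROI if given, else the brain mask) and `condition`
#'   (stimulated block label; default the design's second condition, the
#'   convention for stimulus-after-baseline alternation).
#' @param noise A [noise_spec()].
#' @param n_runs,n_volumes Run structure; 4 runs of 400 volumes at TR 1.5 s
#'   mirrors a resting dual acquisition, 172 volumes a task run.
#' @param seed Master integer seed.
#' @param motion_bounds Named vector `c(translation_um=, rotation_deg=)`
#'   bounding the simulated head-motion traces.
#' @return List with `runs_a`, `runs_b` (lists of `volume_series`) and
#'   `truth` (class `ground_truth`): per-subject `coupling_map` and
#'   `beta_map`, per-run `shared_signal`, the `task_regressor`, and
#'   per-subject/run `motion` traces.
#' @export
simulate_pair <- function(grid, masks, coupling = NULL, task = NULL,
                          noise = noise_spec(), n_runs = 4, n_volumes = 400,
                          seed = 1,
                          motion_bounds = c(translation_um = 140,
                                            rotation_deg = 0.6)) {
  dims <- as.integer(grid$dim)
  stopifnot(length(dims) == 3, n_runs >= 1, n_volumes >= 8)
  vox <- if (!is.null(grid$voxel_size_mm)) grid$voxel_size_mm else c(1, 1, 1)
  tr <- if (!is.null(grid$tr_s)) grid$tr_s else 1.5
  if (inherits(masks, "mask3d")) masks <- list(masks, masks)
  if (length(masks) == 1) masks <- rep(masks, 2)
  for (m in masks)
    if (!identical(dim(m$data), dims)) stop("mask grid mismatch")
  nvox <- prod(dims)

  roi_idx <- integer(0)
  c_amp <- 0
  if (!is.null(coupling)) {
    if (!identical(dim(coupling$roi$data), dims)) stop("ROI grid mismatch")
    roi_idx <- which(coupling$roi$data)
    for (m in masks)
      if (!all(m$data[roi_idx]))
        stop("ROI must lie within the brain mask")
    if (coupling$rho > 0) c_amp <- coupling_amplitude(coupling$rho, noise$sigma)
  }

  x_task <- rep(0, n_volumes)
  task_idx <- integer(0)
  beta <- 0
  if (!is.null(task)) {
    des <- task$design
    stopifnot(inherits(des, "block_design"))
    cond <- if (!is.null(task$condition)) task$condition else
      unique(des$blocks$condition)[min(2, length(unique(des$blocks$condition)))]
    ind <- block_regressor(des, cond)
    if (length(ind) > n_volumes)
      stop("task design longer than n_volumes")
    conv <- convolve_regressor(ind, hrf_kernel(des$tr_s))
    x_task[seq_along(conv)] <- conv
    beta <- task$beta
    troi <- if (!is.null(task$roi)) task$roi else
      if (!is.null(coupling)) coupling$roi else masks[[1]]
    if (!identical(dim(troi$data), dims)) stop("task ROI grid mismatch")
    task_idx <- which(troi$data)
  }

  drift <- poly_drift(n_volumes, noise$drift_coeffs)
  base_t <- noise$baseline * (1 + drift)

  coupling_map <- array(0, dims)
  coupling_map[roi_idx] <- c_amp
  beta_map <- array(0, dims)
  beta_map[task_idx] <- beta

  subj <- c("A", "B")
  runs <- list(A = vector("list", n_runs), B = vector("list", n_runs))
  shared <- vector("list", n_runs)
  motion <- list(A = vector("list", n_runs), B = vector("list", n_runs))

  for (r in seq_len(n_runs)) {
    g <- sample_shared_signal(n_volumes, tr, coupling$band_hz %||% c(0.01, 0.1),
                              seed = derive_seed(seed, sprintf("run%02d/g", r)))
    shared[[r]] <- g
    for (s in 1:2) {
      im <- which(masks[[s]]$data)
      bg <- setdiff(seq_len(nvox), im)
      mat <- matrix(0, nvox, n_volumes)
      with_seed(derive_seed(seed, sprintf("run%02d/%s/noise", r, subj[s])), {
        mat[im, ] <- ar1_noise(length(im), n_volumes, noise$sigma,
                               noise$ar1_phi)
        if (length(bg) > 0 && noise$background_sigma > 0)
          mat[bg, ] <- matrix(stats::rnorm(length(bg) * n_volumes, 0,
                                           noise$background_sigma),
                              length(bg), n_volumes)
      })
      mat[im, ] <- mat[im, ] + rep(base_t, each = length(im))
      if (length(roi_idx) > 0 && c_amp > 0)
        mat[roi_idx, ] <- mat[roi_idx, ] + c_amp * rep(g, each = length(roi_idx))
      if (length(task_idx) > 0 && beta != 0)
        mat[task_idx, ] <- mat[task_idx, ] + beta * rep(x_task,
                                                        each = length(task_idx))
      runs[[s]][[r]] <- volume_series(
        array(mat, c(dims, n_volumes)), voxel_size_mm = vox, tr_s = tr,
        orientation = "LAS", subject_id = subj[s],
        run_id = sprintf("run-%02d", r),
        phase_encode = if (r %% 2 == 1) "LR" else "RL")
      motion[[s]][[r]] <- simulate_motion_trace(
        n_volumes, motion_bounds[["translation_um"]],
        motion_bounds[["rotation_deg"]],
        seed = derive_seed(seed, sprintf("run%02d/%s/motion", r, subj[s])))
    }
  }

  truth <- structure(list(
    coupling_map = list(A = coupling_map, B = coupling_map),
    beta_map = list(A = beta_map, B = beta_map),
    shared_signal = shared, task_regressor = x_task,
    motion = motion, rho = if (is.null(coupling)) 0 else coupling$rho,
    coupling_amplitude = c_amp, beta = beta), class = "ground_truth")
  list(runs_a = runs$A, runs_b = runs$B, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate multi-channel receiver noise samples
#'
#' Draws zero-mean multivariate Gaussian samples with the requested
#' channel-by-channel covariance, emulating a noise-only acquisition (no RF
#' transmission) used to characterize receive-array coupling.
#'
#' @param covariance Symmetric positive semi-definite channel covariance.
#' @param n_samples Number of samples (rows).
#' @param seed Integer seed.
#' @return Numeric matrix `n_samples x n_channels`.
#' @export
simulate_noise_channels <- function(covariance, n_samples, seed = 1) {
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance is not positive semi-definite")
  x <- with_seed(seed,
                 MASS::mvrnorm(n_samples, mu = rep(0, ncol(covariance)),
                               Sigma = covariance, tol = 1e-6))
  colnames(x) <- colnames(covariance) %||%
    paste0("ch", seq_len(ncol(covariance)))
  x
}

#' Simulate a bounded smooth head-motion trace
#'
#' Produces a 6-column motion-parameter trace (3 translations in mm, 3
#' rotations in degrees) as smoothed random walks, zero at the middle
#' (reference) volume and strictly within the given bounds — emulating the
#' residual motion of a well-restrained head.
#'
#' @param n_volumes Number of rows.
#' @param max_translation_um Translation bound in micrometres (per axis).
#' @param max_rotation_deg Rotation bound in degrees (per axis).
#' @param seed Integer seed.
#' @return Matrix `n_volumes x 6` with columns
#'   `tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg`.
#' @export
simulate_motion_trace <- function(n_volumes, max_translation_um = 140,
                                  max_rotation_deg = 0.6, seed = 1) {
  stopifnot(n_volumes >= 1, max_translation_um >= 0, max_rotation_deg >= 0)
  bounds <- c(rep(max_translation_um / 1000, 3), rep(max_rotation_deg, 3))
  ref <- ceiling(n_volumes / 2)
  trace <- with_seed(seed, {
    out <- matrix(0, n_volumes, 6)
    for (j in 1:6) {
      if (bounds[j] == 0 || n_volumes == 1) next
      w <- cumsum(stats::rnorm(n_volumes))
      k <- min(9, n_volumes)
      s <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 2))
      s[is.na(s)] <- w[is.na(s)]
      s <- s - s[ref]
      m <- max(abs(s))
      amp <- bounds[j] * stats::runif(1, 0.4, 0.85)
      out[, j] <- if (m > 0) s / m * amp else 0
    }
    out
  })
  colnames(trace) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  trace
}

#' Synthetic receive-array noise covariance at published magnitudes
#'
#' A synthetic 10-channel covariance (two 5-element coils) whose correlation
#' structure matches the summary magnitudes reported for a dual marmoset
#' receive array: intra-coil correlation mean/max about 12%/28% (coil 1) and
#' 13%/29% (coil 2), maximum inter-coil correlation 2.3%, and a 9.7%
#' relative difference in mean noise level between coils. The raw channel
#' samples behind those summaries are not distributed, so this fixture is a
#' synthetic stand-in constructed from the published values.
#'
#' @return List with `sigma` (10x10 covariance), `coil_of` (channel-to-coil
#'   assignment), `channel_sds`.
#' @export
example_noise_covariance <- function() {
  intra1 <- c(28, 18, 14, 12, 10, 8, 8, 8, 7, 7) / 100   # mean 12%, max 28%
  intra2 <- c(29, 19, 15, 13, 11, 9, 9, 9, 8, 8) / 100   # mean 13%, max 29%
  R <- diag(10)
  pairs <- utils::combn(5, 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    R[i, j] <- R[j, i] <- intra1[p]
    R[i + 5, j + 5] <- R[j + 5, i + 5] <- intra2[p]
  }
  inter <- matrix(0.008, 5, 5)
  inter[1, 1] <- 0.023   # published maximum inter-coil coupling
  R[1:5, 6:10] <- inter
  R[6:10, 1:5] <- t(inter)
  # coil-2 channel SD set so the symmetric relative difference in mean
  # noise level between coils is 9.7%
  s2 <- (1 + 0.097 / 2) / (1 - 0.097 / 2)
  sds <- c(rep(1, 5), rep(s2, 5))
  sigma <- diag(sds) %*% R %*% diag(sds)
  dimnames(sigma) <- list(paste0("ch", 1:10), paste0("ch", 1:10))
  list(sigma = sigma, coil_of = rep(1:2, each = 5), channel_sds = sds)
}
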