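#' Polynomial detrending
#'
#' Removes, per voxel, the least-squares polynomial fit of the given order on
#' time normalized to `[-1, 1]`, using an orthogonal (Legendre-style) basis
#' for numerical stability up to the fifth order used in task modelling.
#' Order 0 removes the mean.
#'
#' @param series A `volume_series` with `t > order + 1`.
#' @param order Polynomial order (>= 0).
#' @return Detrended `volume_series`; every voxel has mean 0.
#' @export
detrend_poly <- function(series, order = 2) {
  n <- n_timepoints(series)
  stopifnot(order >= 0, n > order + 1)
  X <- poly_basis(n, order)
  Q <- qr.Q(qr(X))
  Y <- as_time_matrix(series)
  from_time_matrix(series, Y - Q %*% crossprod(Q, Y))
}

# orthogonal polynomial basis incl. intercept, on normalized time
poly_basis <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  if (order == 0) matrix(1, n, 1) else cbind(1, stats::poly(u, order))
}

#' Temporal band-pass filter
#'
#' Zero-phase frequency-domain filter: unit gain inside `[low_hz, high_hz]`,
#' cosine-tapered transitions extending outward by 30% of each edge
#' frequency, zero gain beyond (so attenuation one octave past either edge
#' well exceeds 20 dB). The DC component is always removed when
#' `low_hz > 0`. The default 0.01-0.1 Hz band is the one used before
#' inter-brain synchrony analysis.
#'
#' @param series A `volume_series`.
#' @param low_hz,high_hz Pass-band edges; `high_hz` must be below Nyquist.
#' @return Filtered `volume_series`.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  n <- n_timepoints(series)
  tr <- series$tr_s
  nyq <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq))
    stop(sprintf("band (%g, %g) Hz invalid for TR %g s (Nyquist %g Hz)",
                 low_hz, high_hz, tr, nyq))
  freq <- seq(0, n - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)
  gain <- bandpass_gain(freq, low_hz, high_hz)
  Y <- as_time_matrix(series)
  Yf <- stats::mvfft(Y) * gain
  from_time_matrix(series, Re(stats::mvfft(Yf, inverse = TRUE)) / n)
}

# cosine-tapered gain profile; exported implicitly through bandpass tests
bandpass_gain <- function(freq, low, high) {
  lo0 <- low * 0.7
  hi1 <- high * 1.3
  g <- numeric(length(freq))
  g[freq >= low & freq <= high] <- 1
  ramp_up <- freq > lo0 & freq < low
  g[ramp_up] <- 0.5 * (1 - cos(pi * (freq[ramp_up] - lo0) / (low - lo0)))
  ramp_dn <- freq > high & freq < hi1
  g[ramp_dn] <- 0.5 * (1 + cos(pi * (freq[ramp_dn] - high) / (hi1 - high)))
  g
}

# separable 1-D Gaussian convolution along one axis of a 3-D array,
# zero-padded (renormalization is handled by the mask denominator)
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1) / 2
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - 1 - r
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + kernel[k] * m[src[ok], ]
  }
  aperm(array(out, d[perm]), order(perm))
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Spatial Gaussian smoothing with mask renormalization
#'
#' Per-volume 3-D Gaussian convolution with
#' `sigma_mm = fwhm / (2 * sqrt(2 * log(2)))`. When a mask is given the
#' kernel is renormalized within it (`smooth(data * mask) / smooth(mask)`),
#' so constant in-mask images are preserved exactly and no out-of-mask
#' signal bleeds in; out-of-mask voxels are returned unchanged. `fwhm_mm = 0`
#' is the identity. 1.5 mm is the resting/synchrony default, 2.0 mm the task
#' pipeline's.
#'
#' @param series A `volume_series`.
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @param mask Optional [mask3d()].
#' @return Smoothed `volume_series`.
#' @export
smooth_gaussian <- function(series, fwhm_mm = 1.5, mask = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(series)
  if (!is.null(mask)) check_same_grid(series, mask)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(a) gauss_kernel_1d(sigma_mm /
                                                       series$voxel_size_mm[a]))
  d <- dim(series$data)
  w <- if (is.null(mask)) array(1, d[1:3]) else
    array(as.numeric(mask$data), d[1:3])
  den <- w
  for (a in 1:3) den <- conv_axis(den, kernels[[a]], a)
  out <- series
  for (t in seq_len(d[4])) {
    vol <- series$data[, , , t]
    num <- vol * w
    for (a in 1:3) num <- conv_axis(num, kernels[[a]], a)
    sm <- vol
    inside <- den > 1e-12
    sm[inside] <- num[inside] / den[inside]
    if (!is.null(mask)) {
      keep <- !mask$data
      sm[keep] <- vol[keep]
    }
    out$data[, , , t] <- sm
  }
  out
}

#' Voxel-wise normalization to mean 0, SD 1
#'
#' Standardizes each voxel's time course (population SD, i.e. divide by n) —
#' the step applied per run before temporal concatenation so that inter-run
#' differences in mean and scale do not bias the inter-brain correlation.
#' Zero-variance voxels are set to all-zero and flagged in the
#' `"degenerate"` attribute rather than raising an error, since background
#' voxels are expected.
#'
#' @param series A `volume_series` with at least 2 time points.
#' @return Normalized `volume_series` with attribute `degenerate`, a 3-D
#'   logical array of flagged voxels.
#' @export
normalize_voxelwise <- function(series) {
  n <- n_timepoints(series)
  stopifnot(n >= 2)
  Y <- as_time_matrix(series)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  sdv <- sqrt(colMeans(Yc^2))
  degen <- sdv <= 1e-12 * pmax(1, abs(mu))
  sdv[degen] <- 1
  Z <- sweep(Yc, 2, sdv, "/")
  Z[, degen] <- 0
  out <- from_time_matrix(series, Z)
  attr(out, "degenerate") <- array(degen, dim(series$data)[1:3])
  out
}

#' Regress nuisance components out of every voxel
#'
#' Projects each voxel's time course onto the orthogonal complement of the
#' given noise components (the downstream half of ICA-based denoising:
#' component time courses labelled as noise are removed by regression).
#' Signal orthogonal to the components is untouched.
#'
#' @param series A `volume_series`.
#' @param components Numeric matrix `t x k` of nuisance time courses,
#'   `k < t`; collinear sets are rejected.
#' @return Residual `volume_series`, orthogonal to every component.
#' @export
regress_nuisance <- function(series, components) {
  components <- as.matrix(components)
  n <- n_timepoints(series)
  if (nrow(components) != n) stop("component length must match the run")
  if (ncol(components) >= n) stop("too many components")
  qrX <- qr(components)
  if (qrX$rank < ncol(components))
    stop(sprintf("nuisance set is rank-deficient (rank %d < %d components)",
                 qrX$rank, ncol(components)))
  Q <- qr.Q(qrX)
  Y <- as_time_matrix(series)
  from_time_matrix(series, Y - Q %*% crossprod(Q, Y))
}

#' Concatenate runs along the time axis
#'
#' Voxel-wise temporal concatenation of same-grid, same-TR runs from one
#' subject; run boundaries are recorded in the `"run_boundaries"` attribute.
#'
#' @param runs List of `volume_series`.
#' @return A single concatenated `volume_series`.
#' @export
concatenate_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  if (length(runs) == 1) {
    out <- runs[[1]]
    attr(out, "run_boundaries") <- n_timepoints(out)
    return(out)
  }
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(dim(r$data)[1:3], dim(ref$data)[1:3]))
      stop("run grids differ")
    if (!isTRUE(all.equal(r$tr_s, ref$tr_s))) stop("run TRs differ")
    if (!identical(r$subject_id, ref$subject_id)) stop("subjects differ")
  }
  nts <- vapply(runs, n_timepoints, integer(1))
  d <- dim(ref$data)[1:3]
  out <- ref
  out$data <- array(unlist(lapply(runs, function(r) r$data),
                           use.names = FALSE), c(d, sum(nts)))
  out$run_id <- paste(vapply(runs, function(r) r$run_id, character(1)),
                      collapse = "+")
  attr(out, "run_boundaries") <- cumsum(nts)
  out
}
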