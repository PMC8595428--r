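#' A block task design
#'
#' Ordered condition blocks with durations commensurate with the TR. The
#' social-viewing paradigm this models alternates 17 blocks — 18 s with
#' opaque smart films (baseline, no visible conspecific) then 12 s
#' transparent (stimulus, visible conspecific) — at TR 1.5 s, i.e. 172
#' volumes per run.
#'
#' @param blocks Data frame (or list of pairs) with columns `condition`
#'   (label) and `duration_s` (> 0, an integer multiple of `tr_s`).
#' @param tr_s Repetition time in seconds.
#' @return Object of class `block_design`.
#' @export
block_design <- function(blocks, tr_s = 1.5) {
  blocks <- as.data.frame(blocks)
  stopifnot(nrow(blocks) >= 1, all(c("condition", "duration_s") %in%
                                     names(blocks)), tr_s > 0)
  nvol <- blocks$duration_s / tr_s
  if (any(blocks$duration_s <= 0) || any(abs(nvol - round(nvol)) > 1e-9))
    stop("block durations must be positive integer multiples of the TR")
  structure(list(blocks = blocks, tr_s = tr_s,
                 n_volumes = as.integer(sum(round(nvol)))),
            class = "block_design")
}

#' The alternating opaque/transparent social-viewing design
#'
#' 17 alternating blocks starting opaque: 9 opaque blocks of 18 s and 8
#' transparent blocks of 12 s at TR 1.5 s (172 volumes, 258 s).
#'
#' @param tr_s Repetition time (default 1.5 s).
#' @return A [block_design()].
#' @export
social_block_design <- function(tr_s = 1.5) {
  cond <- rep(c("opaque", "transparent"), length.out = 17)
  block_design(data.frame(condition = cond,
                          duration_s = ifelse(cond == "opaque", 18, 12)),
               tr_s = tr_s)
}

#' Volume-wise indicator for one condition of a block design
#'
#' @param design A [block_design()].
#' @param condition Condition label.
#' @return 0/1 vector, one entry per volume of the design.
#' @export
block_regressor <- function(design, condition) {
  stopifnot(inherits(design, "block_design"))
  if (!condition %in% design$blocks$condition)
    stop(sprintf("condition '%s' not in design", condition))
  unlist(lapply(seq_len(nrow(design$blocks)), function(i) {
    nv <- round(design$blocks$duration_s[i] / design$tr_s)
    rep(as.numeric(design$blocks$condition[i] == condition), nv)
  }), use.names = FALSE)
}

#' Fixed-shape hemodynamic response kernel
#'
#' Samples of the gamma-variate impulse response
#' `h(t) = t^4 exp(-t) / (4^4 exp(-4))` (unit peak at t = 4 s, h(0) = 0),
#' truncated where `h` falls below `1e-4` of the peak — a single,
#' parameter-free stand-in for block-response bases whose exact
#' parameterization varies between analysis tools.
#'
#' @param tr_s Sampling interval in seconds (> 0).
#' @return Numeric vector `h(0), h(tr), h(2 tr), ...`.
#' @export
hrf_kernel <- function(tr_s) {
  stopifnot(tr_s > 0)
  tt <- seq(0, 60, by = tr_s)
  h <- tt^4 * exp(-tt) / (4^4 * exp(-4))
  last <- max(which(h >= 1e-4))
  h[seq_len(last)]
}

#' Convolve a volume-wise indicator with an HRF kernel
#'
#' Discrete causal convolution, truncated to the indicator's length.
#'
#' @param indicator Numeric vector (e.g. from [block_regressor()]).
#' @param kernel HRF samples (e.g. from [hrf_kernel()]).
#' @return Numeric vector, same length as `indicator`.
#' @export
convolve_regressor <- function(indicator, kernel) {
  n <- length(indicator)
  full <- stats::convolve(indicator, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Assemble a block-design GLM design matrix
#'
#' Columns: one HRF-convolved indicator per condition, orthogonal detrending
#' polynomials up to `detrend_order` (including the intercept), cosine drift
#' regressors for frequencies below `drift_high_hz`, and the 6 motion
#' parameters. Constant (zero-variation) motion columns are dropped with a
#' warning; the assembled matrix is rank-checked and offending columns named
#' on failure.
#'
#' @param design A [block_design()].
#' @param motion Optional `n x 6` motion-parameter matrix.
#' @param detrend_order Polynomial order (default 5).
#' @param drift_high_hz Upper frequency of the cosine drift set (default
#'   0.01 Hz, i.e. everything slower than the temporal filter's pass band).
#' @param n_volumes Run length; defaults to the design's length, may exceed
#'   it (indicators are zero-padded).
#' @return Object of class `design_matrix`: `matrix`, `labels`,
#'   `condition_columns`, `df_residual`.
#' @export
build_design <- function(design, motion = NULL, detrend_order = 5,
                         drift_high_hz = 0.01, n_volumes = NULL) {
  stopifnot(inherits(design, "block_design"))
  n <- if (is.null(n_volumes)) design$n_volumes else n_volumes
  if (n < design$n_volumes) stop("n_volumes shorter than the design")
  kern <- hrf_kernel(design$tr_s)
  conds <- unique(design$blocks$condition)
  cond_cols <- vapply(conds, function(cc) {
    ind <- c(block_regressor(design, cc), rep(0, n - design$n_volumes))
    convolve_regressor(ind, kern)
  }, numeric(n))
  poly <- poly_basis(n, detrend_order)
  colnames(poly) <- paste0("poly", 0:detrend_order)
  k_max <- floor(drift_high_hz * 2 * n * design$tr_s)
  drift <- NULL
  if (k_max >= 1) {
    tix <- seq_len(n) - 0.5
    drift <- vapply(seq_len(k_max),
                    function(k) cos(pi * k * tix / n), numeric(n))
    colnames(drift) <- paste0("drift_cos", seq_len(k_max))
  }
  X <- cbind(cond_cols, poly, drift)
  colnames(X)[seq_along(conds)] <- paste0("cond_", conds)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n) stop("motion trace length must match the run")
    colnames(motion) <- paste0("motion", 1:6)
    keep <- apply(motion, 2, function(v) stats::sd(v) > 1e-12)
    if (!all(keep))
      warning(sprintf("dropping constant motion column(s): %s",
                      paste(colnames(motion)[!keep], collapse = ", ")))
    X <- cbind(X, motion[, keep, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- character(0)
    r <- 0
    for (j in seq_len(ncol(X))) {
      rj <- qr(X[, seq_len(j), drop = FALSE])$rank
      if (rj == r) bad <- c(bad, colnames(X)[j])
      r <- rj
    }
    stop(sprintf("design matrix is rank-deficient; offending columns: %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(matrix = X, labels = colnames(X),
                 condition_columns = paste0("cond_", conds),
                 df_residual = n - qrX$rank),
            class = "design_matrix")
}

#' Write a design matrix as labelled TSV
#' @param design_matrix A `design_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design_matrix, path) {
  write_tsv(as.data.frame(design_matrix$matrix), path)
}

#' Voxel-wise ordinary least squares
#'
#' Fits the design to every voxel: coefficients, standard errors, t values
#' (`coef / se`) and residual variance, with residuals orthogonal to the
#' design by construction.
#'
#' @param series A `volume_series` (or a `t x nvox` numeric matrix).
#' @param design A `design_matrix` (or plain full-rank matrix).
#' @return List: `beta`, `se`, `t` (each `p x nvox`), `sigma2`, `df`,
#'   `labels`.
#' @export
fit_glm <- function(series, design) {
  X <- if (inherits(design, "design_matrix")) design$matrix else
    as.matrix(design)
  Y <- if (inherits(series, "volume_series")) as_time_matrix(series) else
    as.matrix(series)
  if (nrow(Y) != nrow(X)) stop("time lengths of data and design differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank-deficient")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- numeric(ncol(X))
  xtx_inv_diag[qrX$pivot] <- diag(chol2inv(qr.R(qrX)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  list(beta = beta, se = se, t = beta / se, sigma2 = sigma2, df = df,
       labels = colnames(X))
}

#' Convert a t statistic to the equivalent standard-normal deviate
#'
#' `z = qnorm(pt(t, df))`, evaluated through the upper tail for numerical
#' stability, so `z` has the same tail probability as `t` at the given
#' degrees of freedom. At df = 9, t = 2.2622 maps to z = 1.96 (both are the
#' two-sided 5% points).
#'
#' @param t Statistic(s).
#' @param df Degrees of freedom (>= 1).
#' @return z value(s), same shape as `t`.
#' @export
t_to_z <- function(t, df) {
  stopifnot(df >= 1)
  sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE),
                         lower.tail = FALSE)
}

#' Two-sided critical value of Student's t
#' @param alpha Two-sided level (default 0.05).
#' @param df Degrees of freedom.
#' @return Critical value `qt(1 - alpha/2, df)`.
#' @export
critical_t <- function(alpha = 0.05, df) stats::qt(1 - alpha / 2, df)

#' Two-sided critical value of the standard normal
#' @param alpha Two-sided level (default 0.05).
#' @return Critical value `qnorm(1 - alpha/2)`.
#' @export
critical_z <- function(alpha = 0.05) stats::qnorm(1 - alpha / 2)

contrast_result <- function(effect, tval, df, threshold, stat_for_threshold) {
  z <- array(t_to_z(tval, df), dim(as.array(tval)))
  supra <- abs(stat_for_threshold) >= threshold
  structure(list(effect_map = effect, t_map = tval, z_map = z, df = df,
                 threshold = threshold, supra_mask = supra),
            class = "contrast_result")
}

as_effect_matrix <- function(maps) {
  if (is.list(maps)) maps <- vapply(maps, as.vector,
                                    numeric(length(maps[[1]])))
  as.matrix(maps)
}

#' Paired stimulus-versus-baseline contrast across runs
#'
#' Voxel-wise two-sided paired t test of the per-run stimulus coefficient
#' against the per-run baseline coefficient (equivalently, a one-sample t on
#' the per-run differences), df = runs - 1. With 10 runs the two-sided 5%
#' critical value is 2.26.
#'
#' @param stim,base Per-run coefficient maps: `nvox x n_runs` matrices or
#'   lists of equally shaped arrays.
#' @param threshold Threshold applied to `|t|` (default the two-sided 5%
#'   critical value at the available df).
#' @param dims Optional 3-D dims used to reshape the output maps.
#' @return A `contrast_result` (thresholded on the t scale).
#' @export
paired_contrast <- function(stim, base, threshold = NULL, dims = NULL) {
  if (is.list(stim) && is.null(dims)) dims <- dim(stim[[1]])
  S <- as_effect_matrix(stim)
  B <- as_effect_matrix(base)
  stopifnot(identical(dim(S), dim(B)))
  n <- ncol(S)
  if (n < 2) stop("paired contrast needs at least 2 runs")
  D <- S - B
  md <- rowMeans(D)
  sdd <- sqrt(rowSums((D - md)^2) / (n - 1))
  tval <- md / (sdd / sqrt(n))
  tval[sdd == 0] <- 0
  df <- n - 1
  if (is.null(threshold)) threshold <- critical_t(0.05, df)
  shape <- function(v) if (is.null(dims)) v else array(v, dims)
  contrast_result(shape(md), shape(tval), df, threshold, shape(tval))
}

#' Unpaired between-paradigm contrast
#'
#' Voxel-wise two-sample t test between the per-run stimulus coefficients of
#' two paradigms (pooled variance by default, Welch optional), converted to
#' z; thresholded two-sided on `|z|` at 1.96 by default.
#'
#' @param effects_p1,effects_p2 Per-run coefficient maps (`nvox x n_runs`
#'   matrices or lists of arrays), >= 2 runs each.
#' @param threshold z threshold (default 1.96).
#' @param var_equal Pooled variance (default) or Welch.
#' @param dims Optional 3-D dims for the output maps.
#' @return A `contrast_result` (thresholded on the z scale).
#' @export
unpaired_contrast <- function(effects_p1, effects_p2, threshold = 1.96,
                              var_equal = TRUE, dims = NULL) {
  if (is.list(effects_p1) && is.null(dims)) dims <- dim(effects_p1[[1]])
  A <- as_effect_matrix(effects_p1)
  B <- as_effect_matrix(effects_p2)
  n1 <- ncol(A); n2 <- ncol(B)
  if (n1 < 2 || n2 < 2) stop("unpaired contrast needs >= 2 runs per paradigm")
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tval <- (m1 - m2) / se
    tval[se == 0] <- 0
    z <- t_to_z(tval, df)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df_w <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tval <- (m1 - m2) / se
    tval[se == 0] <- 0
    z <- vapply(seq_along(tval),
                function(i) t_to_z(tval[i], max(1, df_w[i])), numeric(1))
    df <- mean(df_w, na.rm = TRUE)
  }
  shape <- function(v) if (is.null(dims)) v else array(v, dims)
  res <- contrast_result(shape(m1 - m2), shape(tval), df, threshold, shape(z))
  res$z_map <- shape(z)
  res
}
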