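#' Temporal signal-to-noise ratio map
#'
#' Per voxel, the ratio of the mean signal of the original time course to the
#' standard deviation of the detrended time course. Detrending (default
#' order 2) removes slow scanner drift that would otherwise inflate the
#' apparent noise. The absolute mean is used so values are nonnegative even
#' at zero-mean background voxels; zero-variance voxels are flagged in the
#' `"degenerate"` attribute and set to 0.
#'
#' @param series A `volume_series` with `t >= detrend_order + 2`.
#' @param detrend_order Polynomial order removed before the SD (>= 0).
#' @return Object of class `tsnr_map`: 3-D `data` array, `detrend_order`,
#'   `subject_id`.
#' @export
tsnr_map <- function(series, detrend_order = 2) {
  n <- n_timepoints(series)
  stopifnot(n >= detrend_order + 2)
  Y <- as_time_matrix(series)
  mu <- colMeans(Y)
  res <- as_time_matrix(detrend_poly(series, detrend_order))
  sdv <- sqrt(colSums(res^2) / (n - 1))
  degen <- sdv <= 1e-12 * pmax(1, abs(mu))
  tsnr <- abs(mu) / ifelse(degen, 1, sdv)
  tsnr[degen] <- 0
  d <- dim(series$data)[1:3]
  structure(list(data = array(tsnr, d), detrend_order = detrend_order,
                 subject_id = series$subject_id,
                 degenerate = array(degen, d)),
            class = "tsnr_map")
}

#' Compare temporal-SNR maps of two subjects
#'
#' Whole-brain (and optional per-ROI) mean tSNR per subject, histograms, and
#' the relative difference
#' `|mu_a - mu_b| / ((mu_a + mu_b) / 2) * 100` (symmetric-mean denominator;
#' the convention is recorded in the output).
#'
#' @param map_a,map_b `tsnr_map` objects on matching grids.
#' @param masks List of two [mask3d()] brain masks.
#' @param rois Optional named list of [mask3d()] ROIs evaluated for both
#'   subjects.
#' @param hist_breaks Histogram bin edges (fixed width).
#' @return List with `table` (per-subject means), `relative_difference_pct`,
#'   `roi_table`, `histograms`, `convention`.
#' @export
tsnr_summary <- function(map_a, map_b, masks, rois = NULL,
                         hist_breaks = seq(0, 200, by = 2)) {
  stopifnot(length(masks) == 2)
  for (i in 1:2)
    if (!identical(dim(list(map_a, map_b)[[i]]$data), dim(masks[[i]]$data)))
      stop("tSNR map and mask grids differ")
  vals <- list(a = map_a$data[masks[[1]]$data & !map_a$degenerate],
               b = map_b$data[masks[[2]]$data & !map_b$degenerate])
  if (any(lengths(vals) == 0)) stop("empty mask")
  mu <- vapply(vals, mean, numeric(1))
  rel <- abs(mu[1] - mu[2]) / ((mu[1] + mu[2]) / 2) * 100
  roi_table <- NULL
  if (!is.null(rois)) {
    roi_table <- do.call(rbind, lapply(names(rois), function(nm) {
      r <- rois[[nm]]$data
      data.frame(roi = nm,
                 mean_a = mean(map_a$data[r & masks[[1]]$data]),
                 mean_b = mean(map_b$data[r & masks[[2]]$data]))
    }))
    roi_table$relative_difference_pct <-
      abs(roi_table$mean_a - roi_table$mean_b) /
      ((roi_table$mean_a + roi_table$mean_b) / 2) * 100
  }
  hists <- lapply(vals, function(v) {
    v <- pmin(pmax(v, min(hist_breaks)), max(hist_breaks))
    h <- graphics::hist(v, breaks = hist_breaks, plot = FALSE)
    data.frame(bin_mid = h$mids, count = h$counts)
  })
  list(table = data.frame(subject = c(map_a$subject_id, map_b$subject_id),
                          mean_tsnr = as.numeric(mu),
                          n_voxels = lengths(vals)),
       relative_difference_pct = as.numeric(rel),
       roi_table = roi_table, histograms = hists,
       convention = "symmetric mean denominator")
}

#' Channel noise-correlation matrix and coil summaries
#'
#' Pearson correlation (in percent) between receiver channels from a
#' noise-only acquisition, partitioned by coil: intra-coil mean and maximum
#' of the absolute off-diagonal correlations per coil, the maximum absolute
#' inter-coil correlation, per-coil mean noise level (mean channel SD), and
#' the symmetric relative difference in mean noise level between coils. Low
#' inter-coil correlation is the hardware guarantee that apparent inter-brain
#' synchrony is not an artifact of coil coupling.
#'
#' @param samples Numeric matrix, samples in rows, channels in columns
#'   (>= 2 channels, >= 10 samples).
#' @param coil_of Integer vector assigning each channel to a coil.
#' @return Object of class `noise_correlation`: `matrix` (percent),
#'   `coil_of`, and a `summary` list.
#' @export
noise_correlation <- function(samples, coil_of) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) >= 2, nrow(samples) >= 10,
            length(coil_of) == ncol(samples))
  sds <- apply(samples, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance channel")
  cm <- stats::cor(samples) * 100
  coils <- sort(unique(coil_of))
  intra <- lapply(coils, function(k) {
    sub <- cm[coil_of == k, coil_of == k, drop = FALSE]
    off <- abs(sub[upper.tri(sub)])
    list(mean = mean(off), max = max(off))
  })
  names(intra) <- paste0("coil", coils)
  inter_max <- if (length(coils) >= 2) {
    max(abs(cm[coil_of == coils[1], coil_of != coils[1], drop = FALSE]))
  } else NA_real_
  level <- vapply(coils, function(k) mean(sds[coil_of == k]), numeric(1))
  level_diff <- if (length(level) == 2)
    abs(diff(level)) / mean(level) * 100 else NA_real_
  structure(list(matrix = cm, coil_of = coil_of,
                 summary = list(intra = intra, inter_coil_max = inter_max,
                                coil_noise_level = level,
                                noise_level_difference_pct = level_diff)),
            class = "noise_correlation")
}

#' Summarize a motion-parameter trace against bounds
#'
#' Per-axis and overall maxima of absolute displacement (translations
#' reported in micrometres, rotations in degrees) relative to the reference
#' volume; the trace passes when every maximum is within its bound. The
#' default bounds — 140 um and 0.6 degrees — are the residual motion a
#' four-point head fixation achieves over a 5-minute run.
#'
#' @param trace Matrix or data frame with 6 columns: 3 translations (mm),
#'   3 rotations (degrees); at least 1 row.
#' @param translation_bound_um,rotation_bound_deg Pass bounds.
#' @return Object of class `motion_summary` with per-axis maxima, overall
#'   maxima and `pass`.
#' @export
motion_summary <- function(trace, translation_bound_um = 140,
                           rotation_bound_deg = 0.6) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6 || nrow(trace) < 1 || !is.numeric(trace))
    stop("trace must be numeric with 6 columns")
  max_abs <- apply(abs(trace), 2, max)
  trans_um <- max_abs[1:3] * 1000
  rot_deg <- max_abs[4:6]
  structure(list(
    max_translation_um = c(trans_um, overall = max(trans_um)),
    max_rotation_deg = c(rot_deg, overall = max(rot_deg)),
    translation_bound_um = translation_bound_um,
    rotation_bound_deg = rotation_bound_deg,
    pass = max(trans_um) <= translation_bound_um &&
      max(rot_deg) <= rotation_bound_deg), class = "motion_summary")
}

#' Read a whitespace-delimited 6-column motion trace
#' @param path Text file, optional header line, 6 numeric columns
#'   (3 translations mm, 3 rotations deg).
#' @return Numeric matrix `n x 6`.
#' @export
read_motion_trace <- function(path) {
  first <- readLines(path, n = 1)
  header <- suppressWarnings(anyNA(as.numeric(strsplit(trimws(first),
                                                       "\\s+")[[1]])))
  m <- as.matrix(utils::read.table(path, header = header))
  if (ncol(m) != 6) stop("malformed motion trace: need 6 columns")
  unname(m)
}

#' Write a motion trace as whitespace-delimited text with a header
#' @param trace `n x 6` matrix (3 translations mm, 3 rotations deg).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_trace <- function(trace, path) {
  colnames(trace) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  utils::write.table(trace, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
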