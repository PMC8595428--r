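#' Voxel-wise correlation between spatially analogous voxels of two subjects
#'
#' Pearson correlation, per in-mask voxel, between the two subjects'
#' (normalized, concatenated) time courses at the same voxel index. Both
#' series must be on the same grid — i.e. already reoriented to a common
#' convention — and have equal length. Out-of-mask voxels are `NA`.
#'
#' @param concat_a,concat_b `volume_series` of the two subjects.
#' @param mask A [mask3d()] on the same grid.
#' @return 3-D array of correlations in `[-1, 1]` (`NA` outside the mask).
#' @export
pairwise_voxel_correlation <- function(concat_a, concat_b, mask) {
  if (!identical(dim(concat_a$data), dim(concat_b$data)))
    stop("subject grids or lengths differ")
  check_same_grid(concat_a, mask)
  n <- n_timepoints(concat_a)
  if (n < 4) stop("need at least 4 time points")
  A <- as_time_matrix(concat_a)
  B <- as_time_matrix(concat_b)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(pmax(r, -1), 1)
  out <- array(NA_real_, dim(mask$data))
  out[mask$data] <- r[as.vector(mask$data)]
  out
}

#' Variance-stabilized Fisher-Z transform
#'
#' `z = atanh(r) * sqrt(n - 3)`: under independence z is approximately
#' standard normal, which is the scale on which a threshold like 3.1 is
#' meaningful (plain `atanh(r)` would need `r ~ 0.9996` to reach 3.1,
#' implausible for BOLD correlations at any realistic length). `r` is clipped
#' to `1 - 1e-12` in magnitude first so identical-series voxels stay finite.
#' Set `scaled = FALSE` for the plain `atanh(r)` transform.
#'
#' @param r Correlation(s), `|r| <= 1`.
#' @param n Number of time points (>= 4).
#' @param scaled Multiply by `sqrt(n - 3)` (default) or return plain
#'   `atanh(r)`.
#' @return z value(s), same shape as `r`.
#' @export
fisher_z <- function(r, n, scaled = TRUE) {
  if (n < 4) stop("n must be at least 4")
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) stop("|r| must be <= 1")
  rc <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(rc)
  if (scaled) z <- z * sqrt(n - 3)
  z
}

#' Full inter-brain synchrony pipeline
#'
#' Per run, each subject's voxel time courses are normalized to mean 0 and
#' SD 1; runs are temporally concatenated; the voxel-wise correlation between
#' spatially analogous voxels is computed; the correlation map is
#' variance-stabilized Fisher-Z transformed with `n` equal to the total
#' concatenated time-point count; and the z map is thresholded (one-sided at
#' +3.1 by default — synchrony is reported as positive shared activity — with
#' a two-sided option). No autocorrelation correction is applied to `n`; see
#' the package vignette for the effective-degrees-of-freedom caveat.
#'
#' @param runs_a,runs_b Equal-length lists of per-run `volume_series` (same
#'   run lengths across subjects).
#' @param mask A [mask3d()].
#' @param threshold z threshold (default 3.1).
#' @param two_sided Threshold `|z|` instead of `z`.
#' @return Object of class `synchrony_result`: `r_map`, `z_map`,
#'   `n_timepoints`, `threshold`, `supra_mask`, `params`.
#' @export
synchrony_pipeline <- function(runs_a, runs_b, mask, threshold = 3.1,
                               two_sided = FALSE) {
  if (length(runs_a) != length(runs_b)) stop("unequal run counts")
  for (r in seq_along(runs_a))
    if (n_timepoints(runs_a[[r]]) != n_timepoints(runs_b[[r]]))
      stop("run lengths differ between subjects")
  ca <- concatenate_runs(lapply(runs_a, normalize_voxelwise))
  cb <- concatenate_runs(lapply(runs_b, normalize_voxelwise))
  n <- n_timepoints(ca)
  r_map <- pairwise_voxel_correlation(ca, cb, mask)
  z_map <- array(NA_real_, dim(r_map))
  z_map[!is.na(r_map)] <- fisher_z(r_map[!is.na(r_map)], n)
  supra <- !is.na(z_map) &
    (if (two_sided) abs(z_map) else z_map) >= threshold
  structure(list(r_map = r_map, z_map = z_map, n_timepoints = n,
                 threshold = threshold, supra_mask = supra,
                 params = list(two_sided = two_sided,
                               normalization = "per-run, population SD",
                               fisher_scaled = TRUE)),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf(
    "<synchrony_result> n = %d timepoints | threshold z >= %g%s | %d supra-threshold of %d in-mask voxels\n",
    x$n_timepoints, x$threshold, if (x$params$two_sided) " (two-sided)" else "",
    sum(x$supra_mask), sum(!is.na(x$z_map))))
  invisible(x)
}

#' Write the maps of a synchrony result as NIfTI plus a JSON sidecar
#'
#' @param result A `synchrony_result`.
#' @param prefix Output path prefix; writes `<prefix>_r.nii.gz`,
#'   `<prefix>_z.nii.gz`, `<prefix>_supra.nii.gz`, `<prefix>.json`.
#' @param voxel_size_mm Voxel size recorded in the headers.
#' @return Character vector of written paths, invisibly.
#' @export
write_synchrony_result <- function(result, prefix, voxel_size_mm = c(1, 1, 1)) {
  wrap <- function(a) {
    a[is.na(a)] <- 0
    volume_series(array(a, c(dim(a), 1)), voxel_size_mm = voxel_size_mm,
                  tr_s = 1, orientation = "LAS")
  }
  paths <- c(paste0(prefix, "_r.nii.gz"), paste0(prefix, "_z.nii.gz"),
             paste0(prefix, "_supra.nii.gz"))
  write_volume(wrap(result$r_map), paths[1])
  write_volume(wrap(result$z_map), paths[2])
  write_volume(wrap(result$supra_mask + 0), paths[3])
  meta <- paste0(prefix, ".json")
  jsonlite::write_json(list(n_timepoints = result$n_timepoints,
                            threshold = result$threshold,
                            two_sided = result$params$two_sided,
                            supra_voxels = sum(result$supra_mask)),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
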