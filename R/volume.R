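#' A 4-D BOLD time series with acquisition geometry
#'
#' Container for one subject's functional run: a 4-D intensity array
#' `(x, y, z, t)` plus the geometry needed downstream — voxel size, repetition
#' time (TR), anatomical orientation of the array axes, and identifiers.
#' 3-D input arrays are promoted to a single time point.
#'
#' @param data Numeric 3-D or 4-D array.
#' @param voxel_size_mm Three positive voxel dimensions in mm.
#' @param tr_s Repetition time in seconds (> 0); 1.5 s is typical for
#'   whole-brain EPI at the field strengths this package targets.
#' @param orientation Three-letter signed axis code (one letter per array
#'   axis from the pairs R/L, A/P, S/I; e.g. `"RAS"`, `"LPI"`). One of the 48
#'   signed axis permutations.
#' @param subject_id,run_id Identifier strings.
#' @param phase_encode Phase-encode axis and polarity, e.g. `"LR"` or `"RL"`.
#'   Opposing polarities distort oppositely, which is why face-to-face
#'   acquisitions alternate them.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm = c(1, 1, 1), tr_s = 1.5,
                          orientation = "LAS", subject_id = "", run_id = "",
                          phase_encode = "LR") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3-D or 4-D array")
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            length(tr_s) == 1, tr_s > 0, dim(data)[4] >= 1)
  check_orientation(orientation)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = as.numeric(tr_s), orientation = orientation,
                 subject_id = subject_id, run_id = run_id,
                 phase_encode = phase_encode),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %dx%dx%d voxels x %d volumes | voxel %s mm | TR %g s | %s | subject '%s' run '%s' PE %s\n",
    d[1], d[2], d[3], d[4], paste(x$voxel_size_mm, collapse = "x"),
    x$tr_s, x$orientation, x$subject_id, x$run_id, x$phase_encode))
  invisible(x)
}

#' Number of time points of a series
#' @param series A `volume_series`.
#' @return Integer time-axis length.
#' @export
n_timepoints <- function(series) dim(series$data)[4]

#' A 3-D boolean mask on a voxel grid
#'
#' @param data Logical (or coercible) 3-D array with at least one `TRUE`
#'   voxel.
#' @param voxel_size_mm Three positive voxel dimensions in mm.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(data, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3-D array")
  data <- array(as.logical(data), dim(data))
  if (!any(data)) stop("mask has no TRUE voxel")
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "mask3d")
}

check_same_grid <- function(series, mask) {
  if (!identical(dim(series$data)[1:3], dim(mask$data)))
    stop("mask grid does not match series grid")
  invisible(TRUE)
}

# time-major matrix view (t x nvox) used by every voxel-wise operation
as_time_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# rebuild a series from a t x nvox matrix, preserving metadata
from_time_matrix <- function(series, m) {
  d <- dim(series$data)
  out <- series
  out$data <- array(t(m), dim = d)
  out
}

#' Read a NIfTI-1 volume as a `volume_series`
#'
#' 3-D files (e.g. masks saved as images) are promoted to a single time
#' point. TR is taken from the header's fourth pixdim when present, and the
#' orientation code from the qform/sform.
#'
#' @param path Path to a `.nii` or `.nii.gz` file with 3 or 4 dimensions.
#' @param subject_id,run_id Optional identifiers attached to the result.
#' @return A `volume_series`.
#' @export
read_volume <- function(path, subject_id = "", run_id = "") {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!(nd %in% c(3L, 4L)))
    stop(sprintf("'%s' has %d dimensions; need 3 or 4", path, nd))
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  if (is.na(orient) || !nzchar(orient)) orient <- "RAS"
  volume_series(array(as.numeric(img), dim(img)),
                voxel_size_mm = pd[1:3], tr_s = tr, orientation = orient,
                subject_id = subject_id, run_id = run_id)
}

#' Read a 3-D NIfTI mask
#' @param path NIfTI file; nonzero voxels become `TRUE`.
#' @return A `mask3d`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask3d(v$data[, , , 1] != 0, voxel_size_mm = v$voxel_size_mm)
}

#' Write a `volume_series` (or `mask3d`) as NIfTI-1
#'
#' Geometry (voxel size, TR, orientation) is encoded in the header so
#' [read_volume()] round-trips it.
#'
#' @param x A `volume_series` or `mask3d`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "mask3d"))
    x <- volume_series(array(as.numeric(x$data), dim(x$data)),
                       voxel_size_mm = x$voxel_size_mm, tr_s = 1,
                       orientation = "LAS")
  arr <- x$data
  if (dim(arr)[4] == 1L) {
    d3 <- dim(arr)[1:3]
    arr <- array(arr, d3)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(x$voxel_size_mm, x$tr_s)[seq_len(length(dim(arr)))]
  m <- diag(4)
  m[1:3, 1:3] <- orientation_matrix(x$orientation) %*% diag(x$voxel_size_mm)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
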