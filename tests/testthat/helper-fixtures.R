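# Small in-code fixtures shared across test files.

make_series <- function(dims = c(4, 4, 3), n = 20, fill = NULL, tr_s = 1.5,
                        orientation = "LAS", seed = 42, ...) {
  data <- if (is.null(fill)) {
    set.seed(seed)
    array(rnorm(prod(dims) * n), c(dims, n))
  } else array(fill, c(dims, n))
  volume_series(data, tr_s = tr_s, orientation = orientation, ...)
}

full_mask <- function(dims = c(4, 4, 3)) mask3d(array(TRUE, dims))

box_roi <- function(dims, lo, hi) {
  a <- array(FALSE, dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask3d(a)
}

# one voxel's time course as a plain vector
voxel_ts <- function(series, i, j, k) as.numeric(series$data[i, j, k, ])

# set one voxel's time course
set_voxel <- function(series, i, j, k, ts) {
  series$data[i, j, k, ] <- ts
  series
}
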