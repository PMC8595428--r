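test_that("polynomial detrending annihilates polynomials and centers data", {
  n <- 60
  u <- seq(-1, 1, length.out = n)
  s <- make_series(c(2, 2, 1), n = n, fill = 0)
  s <- set_voxel(s, 1, 1, 1, 5 + 2 * u - 3 * u^3)          # cubic drift
  s <- set_voxel(s, 2, 1, 1, rep(7, n))                    # constant
  d5 <- detrend_poly(s, 5)
  expect_equal(max(abs(voxel_ts(d5, 1, 1, 1))), 0, tolerance = 1e-10)
  d0 <- detrend_poly(s, 0)
  expect_equal(voxel_ts(d0, 2, 1, 1), rep(0, n))
  # every voxel has mean zero afterwards
  s2 <- make_series(c(3, 3, 2), n = 40, seed = 1)
  d <- detrend_poly(s2, 2)
  mm <- apply(d$data, 1:3, mean)
  expect_equal(max(abs(mm)), 0, tolerance = 1e-12)
  expect_error(detrend_poly(make_series(n = 4), 5), "order")
})

test_that("detrending a noisy linear drift matches the least-squares oracle", {
  n <- 50
  set.seed(2)
  tt <- seq_len(n)
  y <- 3 + 0.2 * tt + rnorm(n)
  s <- make_series(c(1, 1, 1), n = n, fill = 0)
  s <- set_voxel(s, 1, 1, 1, y)
  res <- voxel_ts(detrend_poly(s, 1), 1, 1, 1)
  oracle <- residuals(lm(y ~ tt))
  expect_equal(res, unname(oracle), tolerance = 1e-10)
})

test_that("bandpass preserves in-band and suppresses out-of-band sinusoids", {
  n <- 400
  tr <- 1.5
  tt <- (seq_len(n) - 1) * tr
  s <- make_series(c(2, 2, 1), n = n, fill = 0)
  s <- set_voxel(s, 1, 1, 1, sin(2 * pi * 0.05 * tt))   # in band
  s <- set_voxel(s, 2, 1, 1, sin(2 * pi * 0.30 * tt))   # out of band
  s <- set_voxel(s, 1, 2, 1, rep(4, n))                 # DC
  f <- bandpass(s, 0.01, 0.1)
  amp <- function(v, freq) {
    p <- Mod(fft(v))
    2 * max(p[round(freq * n * tr) + 1]) / n
  }
  expect_equal(amp(voxel_ts(f, 1, 1, 1), 0.05), 1, tolerance = 0.05)
  expect_lt(amp(voxel_ts(f, 2, 1, 1), 0.30), 0.1)
  expect_equal(mean(voxel_ts(f, 1, 2, 1)), 0, tolerance = 1e-10)
  expect_error(bandpass(s, 0.05, 0.5), "invalid")
})

test_that("bandpass gain is ~1 in band and <=  -20 dB one octave out", {
  freq <- seq(0, 0.333, by = 1e-4)
  g <- dyadfmri:::bandpass_gain(freq, 0.01, 0.1)
  expect_true(all(g[freq >= 0.01 & freq <= 0.1] == 1))
  expect_true(all(g[freq <= 0.005] <= 0.1))
  expect_true(all(g[freq >= 0.2] <= 0.1))
})

test_that("Gaussian smoothing matches a brute-force convolution oracle", {
  dims <- c(7, 7, 5)
  set.seed(3)
  vol <- array(rnorm(prod(dims)), dims)
  s <- volume_series(array(vol, c(dims, 1)), voxel_size_mm = c(1, 1, 1))
  fwhm <- 2
  sm <- smooth_gaussian(s, fwhm)$data[, , , 1]
  # independent oracle: direct triple-loop convolution with edge
  # renormalization
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(3 * sig))
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sig^2)); k1 <- k1 / sum(k1)
  oracle <- array(0, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    num <- 0; den <- 0
    for (a in off) for (b in off) for (cc in off) {
      ii <- i + a; jj <- j + b; kk <- k + cc
      w <- k1[a + r + 1] * k1[b + r + 1] * k1[cc + r + 1]
      if (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
          kk >= 1 && kk <= dims[3]) {
        num <- num + w * vol[ii, jj, kk]
        den <- den + w
      }
    }
    oracle[i, j, k] <- num / den
  }
  expect_equal(sm, oracle, tolerance = 1e-8)
})

test_that("smoothing identities: fwhm 0, constants, impulse peak, masking", {
  dims <- c(9, 9, 7)
  s <- make_series(dims, n = 2, seed = 4)
  expect_identical(smooth_gaussian(s, 0), s)
  # constant in-mask image is unchanged by the renormalized kernel
  m <- box_roi(dims, c(2, 2, 2), c(8, 8, 6))
  cst <- make_series(dims, n = 1, fill = 0)
  cst$data[, , , 1][m$data] <- 5
  smc <- smooth_gaussian(cst, 2, m)
  expect_equal(smc$data[, , , 1][m$data], rep(5, sum(m$data)),
               tolerance = 1e-12)
  # out-of-mask voxels are untouched and do not bleed in
  cst2 <- cst
  cst2$data[, , , 1][!m$data] <- 1000
  smc2 <- smooth_gaussian(cst2, 2, m)
  expect_equal(smc2$data[, , , 1][m$data], rep(5, sum(m$data)),
               tolerance = 1e-12)
  expect_equal(smc2$data[, , , 1][!m$data], rep(1000, sum(!m$data)))
  # single-voxel impulse: peak equals the renormalized kernel center
  imp <- make_series(dims, n = 1, fill = 0)
  imp <- set_voxel(imp, 5, 5, 4, 1)
  smi <- smooth_gaussian(imp, 2)
  sig <- 2 / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(3 * sig))
  k1 <- exp(-(-r:r)^2 / (2 * sig^2)); k1 <- k1 / sum(k1)
  expect_equal(smi$data[5, 5, 4, 1], k1[r + 1]^3, tolerance = 1e-12)
})

test_that("voxel-wise normalization enforces mean 0, SD 1 and flags degenerates", {
  s <- make_series(c(3, 3, 2), n = 30, seed = 5)
  s <- set_voxel(s, 1, 1, 1, rep(2, 30))  # constant voxel
  z <- normalize_voxelwise(s)
  expect_equal(voxel_ts(z, 1, 1, 1), rep(0, 30))
  expect_true(attr(z, "degenerate")[1, 1, 1])
  expect_false(any(attr(z, "degenerate")[-1]))
  v <- voxel_ts(z, 2, 2, 1)
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-12)
  # idempotence
  z2 <- normalize_voxelwise(z)
  expect_equal(z2$data, z$data, tolerance = 1e-12)
})

test_that("nuisance regression projects out components exactly", {
  n <- 10
  set.seed(6)
  comp <- cbind(sin(1:n), cos(1:n))
  s <- make_series(c(2, 2, 1), n = n, fill = 0)
  s <- set_voxel(s, 1, 1, 1, comp[, 1])                     # pure component
  orth <- residuals(lm(rnorm(n) ~ comp))
  s <- set_voxel(s, 2, 1, 1, orth)                          # orthogonal signal
  mixed <- 2 * comp[, 1] - comp[, 2] + rnorm(n)
  s <- set_voxel(s, 1, 2, 1, mixed)
  r <- regress_nuisance(s, comp)
  expect_equal(max(abs(voxel_ts(r, 1, 1, 1))), 0, tolerance = 1e-10)
  expect_equal(voxel_ts(r, 2, 1, 1), unname(orth), tolerance = 1e-10)
  # normal-equations oracle on the mixed voxel
  P <- comp %*% solve(crossprod(comp)) %*% t(comp)
  expect_equal(voxel_ts(r, 1, 2, 1), as.numeric(mixed - P %*% mixed),
               tolerance = 1e-10)
  # residuals orthogonal to every component
  expect_equal(as.numeric(crossprod(comp, voxel_ts(r, 1, 2, 1))), c(0, 0),
               tolerance = 1e-10)
  expect_error(regress_nuisance(s, cbind(comp[, 1], comp[, 1] * 2)),
               "rank-deficient")
})

test_that("run concatenation adds time, records boundaries, checks grids", {
  runs <- lapply(1:4, function(r) make_series(c(3, 3, 2), n = 400, seed = r,
                                              run_id = paste0("run-", r)))
  cc <- concatenate_runs(runs)
  expect_equal(n_timepoints(cc), 1600L)
  expect_equal(attr(cc, "run_boundaries"), seq(400, 1600, by = 400))
  one <- concatenate_runs(runs[1])
  expect_equal(one$data, runs[[1]]$data)
  bad <- make_series(c(4, 3, 2), n = 400)
  expect_error(concatenate_runs(list(runs[[1]], bad)), "grids differ")
  # permuting run order leaves per-voxel moments of normalized runs unchanged
  zr <- lapply(runs, normalize_voxelwise)
  m1 <- concatenate_runs(zr)
  m2 <- concatenate_runs(zr[c(3, 1, 4, 2)])
  expect_equal(apply(m1$data, 1:3, mean), apply(m2$data, 1:3, mean),
               tolerance = 1e-12)
  expect_equal(apply(m1$data, 1:3, sd), apply(m2$data, 1:3, sd),
               tolerance = 1e-12)
})

test_that("normalize-then-concatenate yields mean 0, SD near 1", {
  runs <- lapply(1:4, function(r) make_series(c(2, 2, 2), n = 100,
                                              seed = r + 10))
  cc <- concatenate_runs(lapply(runs, normalize_voxelwise))
  Y <- apply(cc$data, 1:3, function(v) c(mean(v), sd(v)))
  expect_equal(max(abs(Y[1, , , ])), 0, tolerance = 1e-12)
  expect_true(all(Y[2, , , ] >= 0.99 & Y[2, , , ] <= 1.01))
})
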