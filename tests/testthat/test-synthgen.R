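test_that("coupling_amplitude solves c^2/(c^2+sigma^2) = rho", {
  expect_equal(coupling_amplitude(0, 1), 0)
  expect_equal(coupling_amplitude(0.5, 1), 1)
  expect_error(coupling_amplitude(1, 1), "rho")
  # analytic identity across a range
  for (rho in c(0.1, 0.3, 0.7, 0.95)) for (sigma in c(0.5, 2)) {
    cc <- coupling_amplitude(rho, sigma)
    expect_equal(cc^2 / (cc^2 + sigma^2), rho)
  }
})

test_that("coupling_amplitude induces the target correlation (Monte Carlo)", {
  cc <- coupling_amplitude(0.3, 2)
  set.seed(101)
  n <- 1e6
  g <- rnorm(n)
  r <- cor(cc * g + rnorm(n, 0, 2), cc * g + rnorm(n, 0, 2))
  expect_lt(abs(r - 0.3), 0.005)
})

test_that("shared signal is deterministic, standardized, band-limited", {
  g1 <- sample_shared_signal(1600, 1.5, c(0.01, 0.1), seed = 5)
  g2 <- sample_shared_signal(1600, 1.5, c(0.01, 0.1), seed = 5)
  expect_identical(g1, g2)
  expect_equal(mean(g1), 0, tolerance = 1e-12)
  expect_equal(sd(g1), 1, tolerance = 1e-12)
  # periodogram mass fraction inside the band, via a direct FFT
  p <- Mod(fft(g1))^2
  f <- (0:1599) / (1600 * 1.5)
  f <- pmin(f, 1 / 1.5 - f)
  frac <- sum(p[f >= 0.01 & f <= 0.1]) / sum(p[-1])
  expect_gt(frac, 0.95)
  expect_error(sample_shared_signal(1600, 1.5, c(0.2, 0.5)), "Nyquist|invalid")
})

test_that("noise-free limit reproduces baseline and drift exactly", {
  grid <- list(dim = c(4, 4, 3), voxel_size_mm = c(1, 1, 1), tr_s = 1.5)
  ns <- noise_spec(baseline = 100, sigma = 0, ar1_phi = 0,
                   drift_coeffs = c(0.02, -0.01), background_sigma = 0)
  sim <- simulate_pair(grid, full_mask(), coupling = NULL, task = NULL,
                       noise = ns, n_runs = 1, n_volumes = 50, seed = 1)
  u <- seq(-1, 1, length.out = 50)
  expected <- 100 * (1 + 0.02 * u - 0.01 * u^2)
  expect_equal(voxel_ts(sim$runs_a[[1]], 2, 3, 1), expected)
  expect_equal(voxel_ts(sim$runs_b[[1]], 4, 4, 3), expected)
})

test_that("simulated coupling recovers rho voxel-wise at n = 1600", {
  dims <- c(8, 8, 6)
  grid <- list(dim = dims, voxel_size_mm = c(1, 1, 1), tr_s = 1.5)
  roi <- box_roi(dims, c(2, 2, 2), c(7, 7, 5))
  ns <- noise_spec(drift_coeffs = numeric(0))  # isolate the coupling model
  sim <- simulate_pair(grid, full_mask(dims),
                       coupling = coupling_spec(roi, 0.5), noise = ns,
                       n_runs = 4, n_volumes = 400, seed = 3)
  ca <- concatenate_runs(lapply(sim$runs_a, normalize_voxelwise))
  cb <- concatenate_runs(lapply(sim$runs_b, normalize_voxelwise))
  r <- pairwise_voxel_correlation(ca, cb, roi)
  rv <- r[roi$data]
  expect_gt(mean(abs(rv - 0.5) <= 0.04), 0.95)
  # outside the ROI the subjects are independent
  out <- pairwise_voxel_correlation(ca, cb, full_mask(dims))[!roi$data]
  expect_lt(abs(median(out)), 0.01)
})

test_that("AR(1) noise matches phi and sigma; streams are reproducible", {
  grid <- list(dim = c(3, 3, 2), voxel_size_mm = c(1, 1, 1), tr_s = 1.5)
  ns <- noise_spec(sigma = 2, ar1_phi = 0.4, drift_coeffs = numeric(0))
  sim <- simulate_pair(grid, full_mask(c(3, 3, 2)), noise = ns, n_runs = 1,
                       n_volumes = 4000, seed = 8)
  x <- voxel_ts(sim$runs_a[[1]], 1, 1, 1) - 100
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.4), 0.05)
  expect_lt(abs(sd(x) - 2), 0.15)
  sim2 <- simulate_pair(grid, full_mask(c(3, 3, 2)), noise = ns, n_runs = 1,
                        n_volumes = 4000, seed = 8)
  expect_identical(sim$runs_a[[1]]$data, sim2$runs_a[[1]]$data)
  expect_identical(sim$truth$motion, sim2$truth$motion)
})

test_that("noise-free task series regresses back to the exact beta", {
  dims <- c(4, 4, 2)
  grid <- list(dim = dims, voxel_size_mm = c(1, 1, 1), tr_s = 1.5)
  roi <- box_roi(dims, c(1, 1, 1), c(2, 2, 2))
  ns <- noise_spec(sigma = 0, ar1_phi = 0, drift_coeffs = numeric(0),
                   background_sigma = 0)
  des <- social_block_design()
  sim <- simulate_pair(grid, full_mask(dims), task = list(design = des,
                                                          beta = 3,
                                                          roi = roi),
                       noise = ns, n_runs = 1, n_volumes = 172, seed = 2)
  x <- sim$truth$task_regressor
  y <- voxel_ts(sim$runs_a[[1]], 1, 1, 1)
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 1e-10)
  # outside the task ROI: no task response
  y0 <- voxel_ts(sim$runs_a[[1]], 4, 4, 2)
  expect_equal(sd(y0), 0, tolerance = 1e-12)
})

test_that("ground-truth maps are zero outside their ROIs", {
  dims <- c(6, 6, 4)
  grid <- list(dim = dims, voxel_size_mm = c(1, 1, 1), tr_s = 1.5)
  roi <- box_roi(dims, c(2, 2, 2), c(4, 4, 3))
  sim <- simulate_pair(grid, full_mask(dims),
                       coupling = coupling_spec(roi, 0.4),
                       n_runs = 1, n_volumes = 40, seed = 4)
  expect_true(all(sim$truth$coupling_map$A[!roi$data] == 0))
  expect_true(all(sim$truth$coupling_map$A[roi$data] > 0))
  expect_equal(sapply(sim$truth$shared_signal, sd), 1, tolerance = 1e-12)
  expect_error(simulate_pair(grid, box_roi(dims, c(3, 3, 2), c(4, 4, 3)),
                             coupling = coupling_spec(roi, 0.4),
                             n_runs = 1, n_volumes = 40),
               "ROI must lie within")
})

test_that("noise channel sampler matches its target covariance", {
  # independent channels: off-diagonals bounded by sampling error
  x <- simulate_noise_channels(diag(4), 1e5, seed = 7)
  cm <- cor(x)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.02)
  # duplicated channel via a rank-1 block
  sig <- diag(3); sig[1, 2] <- sig[2, 1] <- 1
  y <- simulate_noise_channels(sig, 1000, seed = 7)
  expect_equal(cor(y)[1, 2], 1)
  expect_error(simulate_noise_channels(matrix(c(1, 2, 2, 1), 2), 100),
               "positive semi-definite")
  expect_error(simulate_noise_channels(matrix(c(1, 2, 0, 1), 2), 100),
               "symmetric")
})

test_that("fixture covariance reproduces the published coil summaries", {
  nc <- example_noise_covariance()
  x <- simulate_noise_channels(nc$sigma, 2e5, seed = 11)
  res <- noise_correlation(x, nc$coil_of)
  expect_equal(res$summary$intra$coil1$max, 28, tolerance = 0.05)
  expect_equal(res$summary$inter_coil_max, 2.3, tolerance = 0.15)
  expect_equal(res$summary$noise_level_difference_pct, 9.7, tolerance = 0.05)
})

test_that("motion traces are smooth, bounded, deterministic", {
  m <- simulate_motion_trace(200, 140, 0.6, seed = 13)
  expect_equal(dim(m), c(200L, 6L))
  expect_lt(max(abs(m[, 1:3])) * 1000, 140)
  expect_lt(max(abs(m[, 4:6])), 0.6)
  expect_true(motion_summary(m)$pass)
  expect_identical(m, simulate_motion_trace(200, 140, 0.6, seed = 13))
  z <- simulate_motion_trace(50, 0, 0, seed = 13)
  expect_true(all(z == 0))
})
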