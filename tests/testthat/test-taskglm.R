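test_that("the 17-block 18s/12s design spans 172 volumes at TR 1.5 s", {
  des <- social_block_design()
  expect_equal(des$n_volumes, 172L)
  trans <- block_regressor(des, "transparent")
  expect_equal(length(trans), 172L)
  expect_equal(sum(trans), 64)                       # 8 blocks x 8 volumes
  opq <- block_regressor(des, "opaque")
  expect_equal(sum(opq), 108)                        # 9 blocks x 12 volumes
  expect_equal(trans + opq, rep(1, 172))
  one <- block_design(data.frame(condition = "on", duration_s = 9), tr_s = 1.5)
  expect_equal(block_regressor(one, "on"), rep(1, 6))
  expect_error(block_design(data.frame(condition = "on", duration_s = 10),
                            tr_s = 1.5), "multiples")
  expect_error(block_regressor(des, "nope"), "not in design")
})

test_that("HRF kernel peaks at 1 at t = 4 s and starts at 0", {
  k <- hrf_kernel(0.5)
  expect_equal(k[1], 0)
  expect_equal(k[9], 1)                              # t = 4 s
  expect_equal(which.max(k), 9L)
  expect_true(all(k >= 0))
  expect_lt(k[length(k)], 1e-3)
  # matches the analytic form everywhere
  tt <- (seq_along(k) - 1) * 0.5
  expect_equal(k, tt^4 * exp(-tt) / (4^4 * exp(-4)))
})

test_that("regressor convolution matches a brute-force sum oracle", {
  tr <- 1.5
  ind <- c(rep(0, 4), rep(1, 8), rep(0, 12))        # a 12-s boxcar
  kern <- hrf_kernel(tr)
  mine <- convolve_regressor(ind, kern)
  oracle <- vapply(seq_along(ind), function(t)
    sum(vapply(seq_along(kern), function(k)
      if (t - k + 1 >= 1) kern[k] * ind[t - k + 1] else 0, numeric(1))),
    numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-10)
})

test_that("design matrix has the documented composition and full rank", {
  des <- social_block_design()
  set.seed(1)
  mot <- simulate_motion_trace(172, 140, 0.6, seed = 2)
  X <- build_design(des, motion = mot)
  # 2 conditions + 6 polynomials + 5 cosine drifts (f < 0.01 Hz) + 6 motion
  expect_equal(ncol(X$matrix), 19L)
  expect_equal(qr(X$matrix)$rank, 19L)
  expect_equal(X$df_residual, 172L - 19L)
  expect_setequal(X$condition_columns, c("cond_opaque", "cond_transparent"))
  expect_warning(build_design(des, motion = matrix(0, 172, 6)),
                 "constant motion")
})

test_that("OLS fit matches the normal-equations oracle and recovers beta", {
  # 10-timepoint single-voxel example against an explicit solve
  set.seed(2)
  X <- cbind(1, rnorm(10), rnorm(10))
  y <- matrix(rnorm(10), 10, 1)
  fit <- fit_glm(y, X)
  oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-10)
  res <- y - X %*% fit$beta
  expect_equal(as.numeric(crossprod(X, res)), rep(0, 3), tolerance = 1e-8)
  s2 <- sum(res^2) / (10 - 3)
  se_o <- sqrt(diag(solve(crossprod(X))) * s2)
  expect_equal(as.numeric(fit$se), se_o, tolerance = 1e-10)
  # noise-free block data returns the exact beta
  des <- social_block_design()
  Xd <- build_design(des)
  ysig <- 100 + 2 * Xd$matrix[, "cond_transparent"]
  fit2 <- fit_glm(matrix(ysig), Xd)
  expect_equal(unname(fit2$beta["cond_transparent", 1]), 2, tolerance = 1e-8)
  expect_equal(unname(fit2$beta["cond_opaque", 1]), 0, tolerance = 1e-8)
})

test_that("null t statistics follow Student's t at the residual df", {
  set.seed(3)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  Y <- matrix(rnorm(n * 2000), n, 2000)
  fit <- fit_glm(Y, X)
  ks <- ks.test(fit$t[2, ], pt, df = fit$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("condition estimates are invariant to nuisance contamination", {
  des <- social_block_design()
  set.seed(4)
  mot <- simulate_motion_trace(172, 140, 0.6, seed = 5)
  X <- build_design(des, motion = mot)
  y <- 100 + 2 * X$matrix[, "cond_transparent"] + rnorm(172)
  fit1 <- fit_glm(matrix(y), X)
  # add a linear combination of nuisance columns to the data
  contam <- y + 3 * X$matrix[, "poly2"] - 5 * X$matrix[, "motion1"] +
    0.5 * X$matrix[, "drift_cos1"]
  fit2 <- fit_glm(matrix(contam), X)
  for (cc in X$condition_columns) {
    expect_equal(fit1$beta[cc, 1], fit2$beta[cc, 1], tolerance = 1e-8)
    expect_equal(fit1$t[cc, 1], fit2$t[cc, 1], tolerance = 1e-6)
  }
  # permuting column order leaves fitted condition effects unchanged
  perm <- sample(ncol(X$matrix))
  Xp <- X$matrix[, perm]
  fit3 <- fit_glm(matrix(y), Xp)
  expect_equal(fit3$beta["cond_transparent", 1],
               fit1$beta["cond_transparent", 1], tolerance = 1e-8)
})

test_that("paired contrast equals the closed-form paired t", {
  set.seed(5)
  stim <- matrix(rnorm(30, mean = 1), 3, 10)      # 3 voxels x 10 runs
  base <- matrix(rnorm(30), 3, 10)
  pc <- paired_contrast(stim, base)
  expect_equal(pc$df, 9)
  expect_equal(pc$threshold, qt(0.975, 9), tolerance = 1e-12)
  for (v in 1:3) {
    o <- t.test(stim[v, ], base[v, ], paired = TRUE)
    expect_equal(pc$t_map[v], unname(o$statistic), tolerance = 1e-10)
    expect_equal(pc$effect_map[v], unname(o$estimate), tolerance = 1e-10)
  }
  # identical maps give t = 0; paired t equals one-sample t on differences
  same <- paired_contrast(stim, stim)
  expect_equal(same$t_map, rep(0, 3))
  d <- stim - base
  one <- t.test(d[1, ])
  expect_equal(pc$t_map[1], unname(one$statistic), tolerance = 1e-10)
  expect_error(paired_contrast(stim[, 1, drop = FALSE],
                               base[, 1, drop = FALSE]), "at least 2")
})

test_that("unpaired contrast matches the pooled two-sample t and Welch", {
  set.seed(6)
  a <- matrix(rnorm(25, 1), 5, 5)
  b <- matrix(rnorm(25), 5, 5)
  uc <- unpaired_contrast(a, b)
  expect_equal(uc$df, 8)
  for (v in 1:5) {
    o <- t.test(a[v, ], b[v, ], var.equal = TRUE)
    expect_equal(uc$t_map[v], unname(o$statistic), tolerance = 1e-10)
  }
  w <- unpaired_contrast(a, b, var_equal = FALSE)
  ow <- t.test(a[1, ], b[1, ])
  expect_equal(w$t_map[1], unname(ow$statistic), tolerance = 1e-10)
  expect_error(unpaired_contrast(a[, 1, drop = FALSE], b), ">= 2 runs")
})

test_that("unpaired null calibration: |z| > 1.96 in ~5% of voxels", {
  set.seed(7)
  nv <- 20000
  a <- matrix(rnorm(nv * 5), nv, 5)
  b <- matrix(rnorm(nv * 5), nv, 5)
  uc <- unpaired_contrast(a, b, threshold = 1.96)
  frac <- mean(abs(uc$z_map) > 1.96)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nv))
  expect_equal(mean(uc$supra_mask), frac)
})

test_that("t-to-z conversion preserves tail probability", {
  expect_equal(t_to_z(0, 9), 0)
  expect_equal(t_to_z(1.96, 1e6), 1.96, tolerance = 1e-4)
  # t = 2.2622 at df 9 and z = 1.96 are both the two-sided 5% points
  expect_equal(t_to_z(2.2622, 9), 1.96, tolerance = 1e-3)
  # tail equivalence against the distribution functions directly
  for (tv in c(-3, -0.5, 0.7, 4)) {
    z <- t_to_z(tv, 7)
    expect_equal(pnorm(z), pt(tv, 7), tolerance = 1e-12)
  }
  # numerically stable far in the tail
  expect_true(is.finite(t_to_z(15, 200)))
  expect_equal(round(critical_t(0.05, 9), 2), 2.26)
  expect_equal(round(critical_z(0.05), 2), 1.96)
})
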