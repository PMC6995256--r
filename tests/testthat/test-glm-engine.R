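test_that("the canonical HRF starts at zero, peaks near 5 s, net positive", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(tg[which.max(h)], 5, tolerance = 0.02)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_gt(sum(h) * 0.01, 0)
})

test_that("the design matrix has the documented structure", {
  sch <- default_schedule()
  X <- build_design(sch, n_volumes = 246, tr_s = 2.6)
  expect_equal(nrow(X), 246)
  # floor(2 * (246 * 2.6) / 128) = 9 drift regressors
  expect_equal(sum(grepl("^drift_", colnames(X))), 9)
  expect_true(all(c("body", "non_body", "intercept") %in% colnames(X)))
  expect_equal(qr(unclass(X))$rank, ncol(X))

  # drift columns orthonormal
  D <- X[, grepl("^drift_", colnames(X))]
  expect_equal(crossprod(D), diag(9), tolerance = 1e-8,
               ignore_attr = TRUE)

  # motion covariate: centered cumulative motion per stimulus block
  stim <- sch$blocks[sch$blocks$condition_class != "baseline", ]
  bm <- data.frame(block_id = stim$block_id,
                   cumulative_motion = seq_len(nrow(stim)) * 10)
  Xm <- build_design(sch, block_motions = bm, n_volumes = 246)
  expect_true("motion_covariate" %in% colnames(Xm))
  expect_equal(qr(unclass(Xm))$rank, ncol(Xm))

  # identical motions center to an all-zero covariate column
  bm$cumulative_motion <- 500
  Xz <- build_design(sch, block_motions = bm, n_volumes = 246)
  expect_equal(max(abs(Xz[, "motion_covariate"])), 0)

  # head motion columns are mean-centered
  set.seed(1)
  hm <- matrix(rnorm(246 * 6, mean = 3), 246, 6)
  Xh <- build_design(sch, head_motion = hm, n_volumes = 246)
  expect_equal(colMeans(Xh[, grepl("motion_param", colnames(Xh))]),
               rep(0, 6), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(build_design(sch, n_volumes = 100, tr_s = 2.6), "longer")
  expect_error(build_design(sch, head_motion = hm[, 1:3], n_volumes = 246),
               "6")
})

test_that("Gaussian smoothing preserves mass and has the nominal width", {
  v <- array(0, c(15, 15, 15)); v[8, 8, 8] <- 1
  expect_identical(smooth_volume(v, fwhm_mm = 0), v)
  sv <- smooth_volume(v, fwhm_mm = 8, voxel_size_mm = 3)
  expect_equal(sum(sv), 1, tolerance = 1e-6)
  # empirical sd of the kernel along one axis, in mm:
  # fwhm / (2 sqrt(2 log 2)) = 3.3973 mm for 8 mm FWHM
  prof <- apply(sv, 1, sum)
  mu <- sum((1:15) * prof)
  sd_vox <- sqrt(sum((1:15 - mu)^2 * prof))
  expect_equal(sd_vox * 3, 8 / (2 * sqrt(2 * log(2))), tolerance = 1e-3)
  expect_error(smooth_volume(v, 8, voxel_size_mm = 0), "positive")

  # 4D volumes are smoothed frame-wise
  v4 <- array(0, c(9, 9, 9, 2)); v4[5, 5, 5, 1] <- 1; v4[5, 5, 5, 2] <- 2
  sv4 <- smooth_volume(v4, 8, 3)
  expect_equal(sv4[, , , 2], 2 * sv4[, , , 1], tolerance = 1e-12)
})

test_that("DCT high-pass filtering removes drifts and the mean", {
  expect_equal(highpass_filter(rep(3.14, 246)), rep(0, 246),
               tolerance = 1e-10)
  # a pure in-basis drift component vanishes
  n <- 246
  B <- dynbodyloc:::dct_basis(n, 3)
  expect_equal(highpass_filter(5 * B[, 2], 128, 2.6), rep(0, n),
               tolerance = 1e-10)
  # white-noise variance reduced by (K + 1) / n on average (mean + K
  # drift dimensions projected out)
  K <- dynbodyloc:::n_dct_columns(n, 2.6, 128)
  set.seed(2)
  ratios <- replicate(200, {
    y <- rnorm(n)
    sum(highpass_filter(y, 128, 2.6)^2) / sum(y^2)
  })
  expect_equal(mean(ratios), 1 - (K + 1) / n, tolerance = 0.01)
  expect_error(highpass_filter(1:10, cutoff_s = 4, tr_s = 2.6), "cutoff")
  expect_error(highpass_filter(3, 128, 2.6), "2 samples")
})

test_that("voxelwise OLS matches the normal-equations oracle", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
  colnames(X) <- c("intercept", "a", "b", "c")
  B0 <- matrix(rnorm(4 * 50), 4, 50)
  Y <- X %*% B0
  fit <- fit_glm(Y, X)
  expect_equal(fit$beta, B0, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(fit$sigma2), 1e-20)

  Yn <- Y + matrix(rnorm(20 * 50), 20, 50)
  fit <- fit_glm(Yn, X)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% Yn
  expect_lt(max(abs(fit$beta - beta_oracle)), 1e-10)
  expect_equal(fit$df_resid, 16)

  # residuals orthogonal to every design column
  resid <- Yn - X %*% fit$beta
  expect_lt(max(abs(t(X) %*% resid)), 1e-8 * max(abs(Yn)))

  # permuting voxels permutes outputs identically
  perm <- sample(50)
  fit_p <- fit_glm(Yn[, perm], X)
  expect_equal(fit_p$beta, fit$beta[, perm], tolerance = 1e-12)
  expect_equal(fit_p$sigma2, fit$sigma2[perm], tolerance = 1e-12)

  # rank deficiency: duplicated column -> warning, reduced df
  Xd <- cbind(X, dup = X[, "a"])
  expect_warning(fitd <- fit_glm(Yn, Xd), "rank deficient")
  expect_equal(fitd$df_resid, 16)

  expect_error(fit_glm(Yn[1:3, ], X[1:3, ]), "more volumes")
})

test_that("contrast t-maps follow the definitional formula", {
  set.seed(4)
  n <- 30; p <- 4
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("intercept", "x1", "x2", "x3")
  grid <- c(10, 10, 10)
  Y <- matrix(rnorm(n * prod(grid)), n)
  Y[, 1] <- Y[, 1] + 2 * X[, "x1"]
  fit <- fit_glm(Y, X)
  affine <- grid_affine(grid, 3)
  cc <- c(0, 1, 0, 0)
  map <- contrast_tmap(fit, cc, grid, affine)
  expect_equal(map$df, n - p)

  # independent dense oracle via lm() on a voxel subset
  for (v in c(1, 17, 500, 1000)) {
    sm <- summary(lm(Y[, v] ~ 0 + X))
    expect_equal(as.numeric(map$values)[v],
                 sm$coefficients["Xx1", "t value"], tolerance = 1e-8)
  }

  # zero contrast -> all-zero map
  map0 <- contrast_tmap(fit, c(0, 0, 0, 0), grid, affine)
  expect_true(all(map0$values == 0))

  # named contrasts resolve against design columns
  mapn <- contrast_tmap(fit, c(x1 = 1), grid, affine)
  expect_equal(mapn$values, map$values)
  expect_error(contrast_tmap(fit, c(nope = 1), grid, affine), "unknown")

  # noise-free planted effect: capped t at the planted voxel, zero at
  # constant voxels
  Yc <- matrix(5, n, 8)
  Yc[, 3] <- 5 + X[, "x1"]
  fitc <- fit_glm(Yc, X)
  mc <- contrast_tmap(fitc, cc, c(2, 2, 2), grid_affine(c(2, 2, 2), 3))
  expect_equal(abs(as.numeric(mc$values)[3]), 1e8)
  expect_true(all(as.numeric(mc$values)[-3] == 0))
  expect_true(all(as.vector(mc$zero_variance)[-3]))
})
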