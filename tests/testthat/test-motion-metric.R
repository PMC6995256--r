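test_that("Rec.601 luminance conversion", {
  white <- array(255, c(2, 2, 3))
  expect_equal(to_luminance(white), matrix(255, 2, 2))
  green <- array(rep(c(159, 202, 145), each = 4), c(2, 2, 3))
  expect_equal(to_luminance(green),
               matrix(0.299 * 159 + 0.587 * 202 + 0.114 * 145, 2, 2))
  gray <- array(77, c(3, 4, 3))
  expect_equal(to_luminance(gray), matrix(77, 3, 4))
  expect_error(to_luminance(array(0, c(2, 2, 4))), "3")
})

test_that("colour-keyed background masks match the sweep-union oracle", {
  key <- c(159, 202, 145)
  uni <- array(0, c(4, 5, 3, 2))
  for (ch in 1:3) uni[, , ch, ] <- key[ch]
  expect_true(all(background_mask_from_color(uni, key, tol = 0)))

  cl <- make_clip(small_clip_spec(moving = 20, n_frames = 10), keep_rgb = TRUE)
  mask <- background_mask_from_color(cl$rgb, key, tol = 1)
  # oracle: union of recorded object positions over frames
  occupied <- matrix(FALSE, dim(cl$frames)[1], dim(cl$frames)[2])
  for (t in seq_along(cl$ground_truth$changed)) {
    occupied[cl$ground_truth$changed[[t]]] <- TRUE
  }
  occupied[cl$frames[, , 1] < 100] <- TRUE  # initial object position
  expect_equal(mask, !occupied)
  expect_equal(mask, cl$background_mask)

  noisy <- make_clip(small_clip_spec(moving = 20, n_frames = 5, noise_sd = 2),
                     keep_rgb = TRUE)
  expect_error(background_mask_from_color(noisy$rgb, key, tol = 0), "empty")
})

test_that("background noise estimate matches the half-normal quantile", {
  static <- make_clip(small_clip_spec(moving = 0, noise_sd = 0))
  expect_equal(estimate_noise(static), 0)

  # i.i.d. Gaussian sd sigma: |delta| half-normal, scale sigma*sqrt(2);
  # 95th percentile = qnorm(0.975) * sigma * sqrt(2)
  sigma <- 3
  cl <- make_clip(clip_spec(width = 200, height = 100, n_frames = 20,
                            noise_sd = sigma, moving_pixels_per_frame = 40,
                            seed = 4L))
  expect_gt(sum(cl$background_mask), 1e4)
  theory <- qnorm(0.975) * sigma * sqrt(2)
  expect_lt(abs(estimate_noise(cl) - theory) / theory, 0.05)

  # scale equivariance: doubling sigma doubles the estimate exactly
  # (same seed draws the same standardized noise field)
  cl2 <- make_clip(clip_spec(width = 200, height = 100, n_frames = 20,
                             noise_sd = 2 * sigma, moving_pixels_per_frame = 40,
                             seed = 4L))
  expect_equal(estimate_noise(cl2), 2 * estimate_noise(cl), tolerance = 1e-10)

  expect_error(estimate_noise(structure(list(frames = static$frames,
                                             background_mask = NULL),
                                        class = "video_clip")),
               "mask")
})

test_that("clip motion counts supra-noise pixels and is offset invariant", {
  static <- make_clip(small_clip_spec(moving = 0, noise_sd = 0))
  expect_equal(clip_motion(static, 0)$clip_motion, 0)
  expect_equal(clip_motion(static, 5)$clip_motion, 0)

  cl <- make_clip(clip_spec(width = 200, height = 100, n_frames = 20,
                            noise_sd = 2, moving_pixels_per_frame = 120,
                            seed = 1L))
  mr <- clip_motion(cl)            # thresholds at the realized noise level
  expect_equal(mr$clip_motion, 120)
  expect_equal(mr$per_pair_counts, brute_force_counts(cl, mr$noise_level))
  expect_equal(mr$clip_motion, mean(mr$per_pair_counts))
  expect_length(mr$per_pair_counts, dim(cl$frames)[3] - 1)

  # offset invariance checked at a threshold away from floating-point
  # ties with the realized noise maximum
  shifted <- cl
  shifted$frames <- cl$frames + 17.3
  expect_equal(clip_motion(shifted, 50)$clip_motion,
               clip_motion(cl, 50)$clip_motion)

  # monotone nondecreasing as the threshold decreases; bounded by frame size
  thrs <- c(200, 50, 10, 1, 0)
  counts <- vapply(thrs, function(th) clip_motion(cl, th)$clip_motion,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts >= 0 & counts <= 200 * 100))
})

test_that("block motion is the sum of five clip motions", {
  mk <- function(v) structure(list(noise_level = 0, per_pair_counts = v,
                                   clip_motion = v, label = list()),
                              class = "motion_result")
  res <- lapply(c(3, 1, 4, 1, 5), mk)
  bm <- block_motion(res, "body")
  expect_equal(bm$cumulative_motion, 14)
  expect_equal(block_motion(lapply(rep(0, 5), mk), "object")$cumulative_motion, 0)
  perm <- block_motion(res[c(5, 3, 1, 2, 4)], "body")
  expect_equal(perm$cumulative_motion, bm$cumulative_motion)
  expect_error(block_motion(res[1:4], "body"), "exactly 5")
})

test_that("rating correlation matches the definitional formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  out <- correlate_ratings(x, y)
  # hand arithmetic: sum of cross-deviations 3, each sum of squares 5
  expect_equal(out$r, 3 / 5)
  expect_equal(out$df, 2)
  t_hand <- 0.6 * sqrt(2) / sqrt(1 - 0.36)
  expect_equal(out$t, t_hand)
  expect_equal(out$p, 2 * pt(-t_hand, 2))

  expect_equal(correlate_ratings(x, 2 * x + 1)$r, 1)
  expect_error(correlate_ratings(rep(1, 5), 1:5), "constant")

  # property: matches cov / (sd sd) on random vectors to 1e-12
  set.seed(99)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    r_def <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlate_ratings(a, b)$r, r_def, tolerance = 1e-12)
  }
})

test_that("block-motion comparison is a pooled-variance t test", {
  same <- c(4, 6, 8)
  expect_equal(compare_block_motion(same, same)$t, 0)

  body <- c(10, 12, 14); object <- c(9, 11, 13)
  out <- compare_block_motion(body, object)
  # hand arithmetic: means 12 vs 11, pooled variance 4, se = 2 sqrt(2/3)
  expect_equal(out$t, 1 / (2 * sqrt(2 / 3)))
  expect_equal(out$df, 4)
  swapped <- compare_block_motion(object, body)
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)

  welch <- compare_block_motion(body, c(1, 50, 3), var_equal = FALSE)
  expect_lt(welch$df, 4)   # Welch df shrinks under unequal variances
})
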