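flat_landmarks <- function(n = 10, ls = c(-18, 55), rs = c(18, 55)) {
  data.frame(time_s = 0.11 * (seq_len(n) - 1),
             ls_x = ls[1], ls_y = ls[2], rs_x = rs[1], rs_y = rs[2],
             le_x = -12, le_y = 30, re_x = 20, re_y = 40)
}

test_that("trunk angle follows the inter-shoulder line", {
  expect_equal(trunk_angle_series(flat_landmarks()), rep(0, 10))
  lm45 <- flat_landmarks(ls = c(0, 0), rs = c(10, 10))
  expect_equal(trunk_angle_series(lm45), rep(45, 10))
  expect_error(trunk_angle_series(flat_landmarks(ls = c(1, 2), rs = c(1, 2))),
               "coincident")
})

test_that("trunk angle is translation-invariant and mirror-equivariant", {
  p <- task_sim_params(n_trials = 2, landmark_noise_sd = 0, seed = 13)
  for (tr in simulate_task_landmarks(p)) {
    lm <- tr$landmarks
    th <- trunk_angle_series(lm)
    shifted <- lm
    for (col in c("ls_x", "rs_x")) shifted[[col]] <- shifted[[col]] + 7.3
    for (col in c("ls_y", "rs_y")) shifted[[col]] <- shifted[[col]] - 2.1
    expect_equal(trunk_angle_series(shifted), th, tolerance = 1e-9)

    mirrored <- lm
    mirrored$ls_x <- -lm$rs_x; mirrored$ls_y <- lm$rs_y
    mirrored$rs_x <- -lm$ls_x; mirrored$rs_y <- lm$ls_y
    expect_equal(trunk_angle_series(mirrored), -th, tolerance = 1e-9)
  }
})

test_that("noise-free simulated tilt is recovered exactly", {
  p <- task_sim_params(n_trials = 3, landmark_noise_sd = 0, seed = 14)
  for (tr in simulate_task_landmarks(p)) {
    th <- trunk_angle_series(tr)
    expect_equal(th, tr$true_tilt, tolerance = 1e-9)
    expect_equal(distortion_level(th), sum(abs(tr$true_tilt)),
                 tolerance = 1e-9)
  }
})

test_that("distortion level is the absolute frame sum", {
  expect_equal(distortion_level(rep(0, 40)), 0)
  expect_equal(distortion_level(c(10, -10, 10)), 30)
  expect_equal(distortion_level(rep(10, 39)), 390)
  expect_equal(distortion_level(rep(10, 39), dt = 0.11), 390 * 0.11)
})

test_that("distortion is non-negative, additive and homogeneous", {
  set.seed(15)
  for (i in 1:10) {
    a <- rnorm(25, sd = 10); b <- rnorm(17, sd = 10); c_pos <- runif(1, 0.1, 5)
    expect_gte(distortion_level(a), 0)
    expect_equal(distortion_level(c(a, b)),
                 distortion_level(a) + distortion_level(b), tolerance = 1e-9)
    expect_equal(distortion_level(c_pos * a), c_pos * distortion_level(a),
                 tolerance = 1e-9)
  }
})

test_that("trajectory resampling preserves endpoints and lines", {
  path <- cbind(c(0, 1, 2, 4, 7), c(0, 2, 4, 8, 14))  # collinear, y = 2x
  same <- resample_trajectory(path, nrow(path))
  expect_equal(same, unname(path))
  rs <- resample_trajectory(path, 23)
  expect_equal(rs[1, ], path[1, ]); expect_equal(rs[23, ], path[5, ])
  expect_lt(max(abs(rs[, 2] - 2 * rs[, 1])) / sqrt(5), 1e-9)
  # idempotence at fixed target length
  expect_identical(resample_trajectory(rs, 23), rs)
  expect_error(resample_trajectory(path[1, , drop = FALSE], 5), ">= 2")
  expect_error(resample_trajectory(path, 1), "target_len")
})

test_that("trajectory averaging uses the longest trial and 6 checkpoints", {
  base <- cbind(seq(0, 10, length.out = 40), seq(5, 0, length.out = 40))
  avg_same <- average_trajectory(list(base, base, base))
  expect_equal(avg_same$mean_path, unname(base))
  expect_true(all(avg_same$checkpoints$x_sd == 0))
  expect_true(all(avg_same$checkpoints$y_sd == 0))
  expect_equal(nrow(avg_same$checkpoints), 6L)
  expect_equal(avg_same$checkpoints$frac, seq(0, 1, by = 0.2))

  # two trials mirrored about x = 3 average onto that vertical line
  left <- cbind(3 - seq(0, 2, length.out = 25), seq(0, 8, length.out = 25))
  right <- cbind(3 + seq(0, 2, length.out = 25), seq(0, 8, length.out = 25))
  avg <- average_trajectory(list(left, right))
  expect_lt(max(abs(avg$mean_path[, 1] - 3)), 1e-9)
  expect_error(average_trajectory(list()), "no trials")
})

test_that("elbow height summary reports grasp/release heights", {
  p <- task_sim_params(n_trials = 1, landmark_noise_sd = 0, seed = 16)
  tr <- simulate_task_landmarks(p)
  hs <- elbow_height_summary(tr)
  expect_equal(hs$base$sd, 0)
  expect_equal(hs$end$sd, 0)
  expect_equal(hs$n, 1L)
  path <- elbow_path(tr[[1]])
  expect_equal(hs$base$mean, path[tr[[1]]$grasp_frame, 2])
  expect_equal(hs$end$mean, path[tr[[1]]$release_frame, 2])
  bad <- tr
  bad[[1]]$grasp_frame <- NULL
  expect_error(elbow_height_summary(bad), "annotations")
})
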