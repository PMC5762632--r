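make_signals <- function(acc = matrix(0, 3, 100), gyr = matrix(0, 3, 100)) {
  preprocess_recording(make_recording(acc, gyr), identity_calib())
}

test_that("CoG acceleration transform reproduces rigid-body kinematics", {
  params0 <- neck_model_params(cog_lever_arm = c(0, 0, 0))
  set.seed(61)
  sig <- make_signals(matrix(rnorm(300), 3), matrix(rnorm(300, sd = 2), 3))
  expect_equal(transform_acc_to_cog(sig, params0), sig$lin_acc * 9.80665)

  # constant omega about IS with lever arm along AP: pure centripetal -|w|^2 r
  r <- c(0.1, 0, 0)
  gyr <- matrix(0, 3, 100); gyr[3, ] <- 3
  sig <- make_signals(gyr = gyr)
  a <- transform_acc_to_cog(sig, neck_model_params(cog_lever_arm = r))
  mid <- 20:80  # away from filter/stencil edges
  expect_equal(a[1, mid], rep(-9 * 0.1, length(mid)), tolerance = 1e-3)
  expect_lt(max(abs(a[2, mid])), 1e-3)

  # forward-simulation oracle: smooth omega(t), fixed r; compare against
  # numerical differentiation of the simulated point trajectory
  t <- (0:99) * 1e-3
  gyr <- rbind(0.8 * sin(2 * pi * 12 * t), 0.5 * cos(2 * pi * 9 * t),
               0.6 * sin(2 * pi * 15 * t))
  r <- c(0.05, -0.03, 0.08)
  sig <- make_signals(gyr = gyr)
  # world trajectory of the point for a body rotating with omega(t), sensor
  # origin fixed at the world origin
  n <- 100
  Rs <- vector("list", n); Rs[[1]] <- diag(3)
  for (k in 1:(n - 1)) {
    wmid <- (sig$ang_vel[, k] + sig$ang_vel[, k + 1]) / 2
    Rs[[k + 1]] <- Rs[[k]] %*% impactkit:::expm_so3(wmid * 1e-3)
  }
  p <- vapply(1:n, function(k) as.numeric(Rs[[k]] %*% r), numeric(3))
  a_world_num <- t(apply(t(apply(p, 1, five_point_derivative)),
                         1, five_point_derivative))
  a_body_num <- vapply(1:n, function(k)
    as.numeric(t(Rs[[k]]) %*% a_world_num[, k]), numeric(3))
  a_cog <- transform_acc_to_cog(sig, neck_model_params(cog_lever_arm = r))
  mid <- 10:91
  expect_lt(max(abs(a_cog[, mid] - a_body_num[, mid])),
            0.02 * max(abs(a_body_num[, mid])))
})

test_that("head pose integration matches closed forms and round trips", {
  sig <- make_signals()
  traj <- integrate_head_pose(sig)
  expect_equal(traj$orientation[[100]], diag(3))
  expect_equal(traj$position, matrix(0, 3, 100), ignore_attr = TRUE)

  # constant omega = pi rad/s about IS for ~100 ms -> rotation 0.099*pi
  gyr <- matrix(0, 3, 100); gyr[3, ] <- pi
  sig <- make_signals(gyr = gyr)
  traj <- integrate_head_pose(sig)
  ang <- impactkit:::logm_so3(traj$orientation[[100]])
  expect_equal(ang, c(0, 0, pi * 0.099), tolerance = 1e-6)
})

test_that("linkage solver recovers planted joint-angle trajectories", {
  params <- neck_model_params()
  n <- 100; t <- (0:99) * 1e-3
  L <- params$neck_length; h <- params$cog_height

  # stationary head
  sig <- make_signals()
  nmt <- solve_linkage(integrate_head_pose(sig, params), params)
  expect_lt(max(abs(nmt$theta_lr)), 1e-6)
  expect_lt(max(nmt$d), 1e-8)

  # forward kinematics: prescribe theta_lr(t) with the torso base fixed,
  # generate the implied head pose, and solve it back
  th <- 0.4 * sin(2 * pi * 8 * t)          # atlanto-occipital flexion
  B0 <- c(0, 0, -h - L)
  traj <- list(orientation = lapply(th, impactkit:::rot_y),
               position = vapply(th, function(a)
                 as.numeric(B0 + c(0, 0, L) +
                              impactkit:::rot_y(a) %*% c(0, 0, h)),
                 numeric(3)),
               dt = 1e-3)
  class(traj) <- "head_trajectory"
  nmt <- solve_linkage(traj, params)
  expect_lt(sqrt(mean((nmt$theta_lr - th)^2)), 1e-3)
  expect_lt(max(nmt$d), 1e-4)
  # link lengths conserved along the whole trajectory
  neck_len <- sqrt(colSums((nmt$head_base - nmt$torso_base)^2))
  expect_equal(neck_len, rep(L, n), tolerance = 1e-9)
  head_len <- sqrt(colSums((nmt$head_cog - nmt$head_base)^2))
  expect_equal(head_len, rep(h, n), tolerance = 1e-9)

  # pure AP translation with fixed orientation: the minimal-base-motion
  # solution tilts the neck toward the displaced joint, so the geometric
  # construction gives d = sqrt(shift^2 + L^2) - L (> 0), with the
  # head-neck joint absorbing the tilt
  shift <- 0.05 * (1 - cos(2 * pi * 5 * t)) / 2
  traj <- list(orientation = rep(list(diag(3)), n),
               position = rbind(shift, 0, 0), dt = 1e-3)
  class(traj) <- "head_trajectory"
  nmt <- solve_linkage(traj, params)
  expect_equal(nmt$d, sqrt(shift^2 + L^2) - L, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_gt(max(nmt$d), 0)
  # the tilt angle satisfies sin(theta) ~ shift / |J - B0|
  expect_equal(max(abs(nmt$theta_lr)),
               asin(max(shift) / sqrt(max(shift)^2 + L^2)), tolerance = 1e-2)
})

test_that("base offset is invariant to a global rigid rotation of the trajectory", {
  params <- neck_model_params()
  t <- (0:99) * 1e-3
  th <- 0.3 * sin(2 * pi * 6 * t)
  h <- params$cog_height; L <- params$neck_length
  B0 <- c(0, 0, -h - L)
  base_traj <- list(orientation = lapply(th, impactkit:::rot_y),
                    position = vapply(seq_along(th), function(k)
                      as.numeric(B0 + c(0, 0, L) +
                                   impactkit:::rot_y(th[k]) %*% c(0, 0, h) +
                                   c(0.01 * sin(2 * pi * 4 * t[k]), 0, 0)),
                      numeric(3)),
                    dt = 1e-3)
  class(base_traj) <- "head_trajectory"
  d0 <- solve_linkage(base_traj, params)$d

  set.seed(71)
  Q <- random_rotation()
  rot_traj <- base_traj
  rot_traj$orientation <- lapply(base_traj$orientation, function(R) Q %*% R)
  rot_traj$position <- Q %*% base_traj$position
  d1 <- solve_linkage(rot_traj, params)$d
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("trajectory features match brute-force scans and the sign-match rule", {
  params <- neck_model_params()
  sig <- make_signals()
  nmt <- solve_linkage(integrate_head_pose(sig, params), params)
  f <- neck_model_trajectory_features(nmt)
  expect_equal(unname(f["nm_signmatch_lr"]), 100)  # deadband: stationary = 100%
  expect_equal(unname(f["nm_base_offset"]), 0, tolerance = 1e-8)
  expect_length(f, 33)

  # planted opposite-sign series score 0, same-sign score 100
  nmt2 <- nmt
  nmt2$theta_lr <- rep(0.2, 100)
  nmt2$neck_angles[2, ] <- -0.2
  expect_equal(unname(neck_model_trajectory_features(nmt2)["nm_signmatch_lr"]), 0)
  nmt2$neck_angles[2, ] <- 0.1
  expect_equal(unname(neck_model_trajectory_features(nmt2)["nm_signmatch_lr"]), 100)

  # random trajectory: every peak equals an exhaustive scan
  set.seed(81)
  gyr <- matrix(rnorm(300, sd = 2), 3)
  acc <- matrix(rnorm(300, sd = 5), 3)
  sig <- make_signals(acc, gyr)
  nmt <- solve_linkage(integrate_head_pose(sig, params), params)
  f <- neck_model_trajectory_features(nmt)
  expect_equal(unname(f["nm_angle_hn_lr"]), max(abs(nmt$theta_lr)))
  expect_equal(unname(f["nm_base_offset"]), max(nmt$d))
  disp <- sqrt(colSums((nmt$head_cog - nmt$head_cog[, 1])^2))
  expect_equal(unname(f["nm_head_cog_disp"]), max(disp))
})

test_that("coupling ratios honor the deadband and match per-sample recomputation", {
  # alpha_sag = 2 * a_AP exactly, others zero -> mean 2, sd 0, peak 2
  sig <- zero_signals()
  sig$lin_acc[1, ] <- seq(1, 3, length.out = 100)
  sig$ang_acc[2, ] <- 2 * sig$lin_acc[1, ]
  f <- coupling_ratios(sig)
  expect_equal(unname(f["cr_sag_ap_mean"]), 2)
  expect_equal(unname(f["cr_sag_ap_sd"]), 0)
  expect_equal(unname(f["cr_sag_ap_peak"]), 2)

  # all-zero signals: every denominator below the deadband -> all 18 zero
  f0 <- coupling_ratios(zero_signals())
  expect_equal(as.numeric(f0), rep(0, 18))
  expect_true(attr(f0, "degenerate"))

  # random bounded signals vs brute-force recomputation
  set.seed(91)
  sig <- zero_signals()
  sig$lin_acc <- matrix(rnorm(300, sd = 2), 3)
  sig$ang_acc <- matrix(rnorm(300, sd = 100), 3)
  f <- coupling_ratios(sig)
  keep <- abs(sig$lin_acc[3, ]) >= 0.5
  r <- sig$ang_acc[1, keep] / sig$lin_acc[3, keep]
  expect_equal(unname(f["cr_cor_is_mean"]), mean(r))
  expect_equal(unname(f["cr_cor_is_sd"]), sd(r))
  expect_equal(unname(f["cr_cor_is_peak"]), max(abs(r)))
  expect_length(f, 18)
})
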