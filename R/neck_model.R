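#' Head-neck linkage model parameters
#'
#' Two-linkage head-neck-torso kinematic model: a head rigid body attached
#' to a neck link through a universal joint (rotations about the LR axis for
#' the atlanto-occipital joint and the IS axis for the atlanto-axial joint),
#' with the neck base attached to a massive torso assumed to move minimally.
#'
#' @param neck_length Neck link length, metres (default 0.108).
#' @param cog_height Head centre-of-gravity height above the head-neck
#'   joint, metres (default 0.05).
#' @param cog_lever_arm Length-3 numeric, metres: lever arm from the sensor
#'   origin to the head centre of gravity in the anatomical frame. This
#'   device-mounting quantity is a required calibration input; the default
#'   places the mouthguard bite plate about 7 cm anterior and 7 cm inferior
#'   of the head CoG.
#' @return Object of class `neck_model_params`.
#' @export
neck_model_params <- function(neck_length = 0.108, cog_height = 0.05,
                              cog_lever_arm = c(-0.07, 0, 0.07)) {
  if (neck_length <= 0 || cog_height <= 0)
    stop("link lengths must be positive", call. = FALSE)
  stopifnot(length(cog_lever_arm) == 3, all(is.finite(cog_lever_arm)))
  structure(list(neck_length = neck_length, cog_height = cog_height,
                 cog_lever_arm = as.numeric(cog_lever_arm)),
            class = "neck_model_params")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Matrix exponential on SO(3) (Rodrigues formula)
#' @param w Rotation vector (axis times angle), radians.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
expm_so3 <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  K <- skew3(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Matrix logarithm on SO(3)
#' @param R 3 x 3 rotation matrix.
#' @return Rotation vector, radians.
#' @keywords internal
logm_so3 <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-9) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) *
    th / (2 * sin(th))
}

rot_y <- function(th) matrix(c(cos(th), 0, -sin(th),
                               0, 1, 0,
                               sin(th), 0, cos(th)), 3, 3)
rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                               -sin(th), cos(th), 0,
                               0, 0, 1), 3, 3)

#' Transform linear acceleration to the head centre of gravity
#'
#' Rigid-body transform of the sensed linear acceleration to a point at
#' lever arm `r` from the sensor: `a_cog = a_sensor + alpha x r +
#' omega x (omega x r)`, with angular acceleration `alpha` obtained from
#' the five-point-stencil derivative of the angular velocity. Only the
#' linkage-model features use this; all other feature blocks work on the
#' untransformed acceleration to avoid coupling linear and angular content.
#'
#' @param sig An `anatomical_signals` object.
#' @param params A [neck_model_params()] providing `cog_lever_arm`.
#' @return 3 x 100 matrix of CoG linear acceleration in m/s^2.
#' @export
transform_acc_to_cog <- function(sig, params) {
  r <- params$cog_lever_arm
  a <- sig$lin_acc * GRAVITY_MS2
  w <- sig$ang_vel
  al <- sig$ang_acc
  out <- a
  for (k in seq_len(ncol(a))) {
    out[, k] <- a[, k] + cross3(al[, k], r) +
      cross3(w[, k], cross3(w[, k], r))
  }
  out
}

#' Integrate the six-degree-of-freedom head pose
#'
#' Head orientation by per-step exponential-map integration of the
#' body-frame angular velocity (midpoint rule across each 1 ms step), and
#' head CoG position by double trapezoid integration of the world-frame CoG
#' acceleration. Initial conditions: identity orientation, zero velocity,
#' CoG at the origin. Gravity is not modeled: the triggered window is too
#' short to resolve the gravity vector, consistent with the preprocessing
#' chain.
#'
#' @param sig An `anatomical_signals` object.
#' @param params A [neck_model_params()].
#' @return Object of class `head_trajectory`: list of per-sample rotation
#'   matrices `orientation` (head frame to world), `position` (3 x 100, m),
#'   `velocity`, `acceleration_world` (3 x 100).
#' @export
integrate_head_pose <- function(sig, params = neck_model_params()) {
  n <- ncol(sig$lin_acc)
  a_cog <- transform_acc_to_cog(sig, params)
  Rs <- vector("list", n)
  Rs[[1]] <- diag(3)
  w <- sig$ang_vel
  for (k in seq_len(n - 1)) {
    w_mid <- (w[, k] + w[, k + 1]) / 2
    Rs[[k + 1]] <- Rs[[k]] %*% expm_so3(w_mid * sig$dt)
  }
  a_world <- vapply(seq_len(n), function(k) Rs[[k]] %*% a_cog[, k],
                    numeric(3))
  v <- t(apply(a_world, 1, cumulative_trapezoid_integral, dt = sig$dt))
  p <- t(apply(v, 1, cumulative_trapezoid_integral, dt = sig$dt))
  structure(list(orientation = Rs, position = p, velocity = v,
                 acceleration_world = a_world, dt = sig$dt),
            class = "head_trajectory")
}

#' Solve the head-neck linkage along a head trajectory
#'
#' Per sample: the head-base joint is placed `cog_height` below the CoG
#' along the head IS axis; the head-vs-neck relative rotation is decomposed
#' as universal-joint rotations about LR then IS, which leaves a
#' two-parameter family of neck orientations; the family member minimizing
#' the distance between the torso-base point and its position at t = 0 is
#' chosen (the massive-torso assumption), giving six unknowns (two
#' head-neck angles, three neck angles, one base distance) for the six
#' known head degrees of freedom. The per-sample 2-D minimization is solved
#' numerically (bounded quasi-Newton, both universal angles restricted to
#' (-pi/2, pi/2)), warm-started from the previous sample; a sample where
#' the solver fails carries the previous sample's solution and is flagged.
#'
#' @param traj A `head_trajectory` from [integrate_head_pose()].
#' @param params A [neck_model_params()].
#' @return Object of class `neck_trajectory`: per-sample universal joint
#'   angles `theta_lr`, `theta_is` (rad); neck orientation rotation vector
#'   `neck_angles` (3 x n, rad, components about AP/LR/IS); positions of
#'   `torso_base`, `head_base`, `head_cog` (3 x n, m); base offset `d`
#'   (>= 0, m); logical `flagged`; and the model `params`.
#' @export
solve_linkage <- function(traj, params = neck_model_params()) {
  n <- ncol(traj$position)
  h <- params$cog_height
  L <- params$neck_length
  J <- vapply(seq_len(n), function(k)
    traj$position[, k] - traj$orientation[[k]] %*% c(0, 0, h), numeric(3))
  # neutral configuration: base directly below the initial joint along the
  # initial head IS axis (zero angles at t = 0; rotation-covariant anchor)
  B0 <- J[, 1] - traj$orientation[[1]] %*% c(0, 0, L)
  theta <- matrix(0, 2, n)
  neck_ang <- matrix(0, 3, n)
  B <- matrix(0, 3, n)
  d <- numeric(n)
  flagged <- logical(n)
  par <- c(0, 0)
  lim <- pi / 2 - 1e-6
  for (k in seq_len(n)) {
    Rh <- traj$orientation[[k]]
    Jk <- J[, k]
    objective <- function(th) {
      Rn <- Rh %*% rot_z(-th[2]) %*% rot_y(-th[1])
      sum((Jk - Rn %*% c(0, 0, L) - B0)^2)
    }
    fit <- tryCatch(
      stats::optim(par, objective, method = "L-BFGS-B",
                   lower = c(-lim, -lim), upper = c(lim, lim),
                   control = list(factr = 10)),
      error = function(e) NULL)
    if (is.null(fit)) {
      flagged[k] <- TRUE
      if (k > 1) {
        theta[, k] <- theta[, k - 1]
      }
      warning(sprintf("linkage solver failed at sample %d; carried previous solution", k),
              call. = FALSE)
    } else {
      theta[, k] <- fit$par
      par <- fit$par
    }
    Rn <- Rh %*% rot_z(-theta[2, k]) %*% rot_y(-theta[1, k])
    neck_ang[, k] <- logm_so3(Rn)
    B[, k] <- Jk - Rn %*% c(0, 0, L)
    d[k] <- sqrt(sum((B[, k] - B0)^2))
  }
  structure(list(theta_lr = theta[1, ], theta_is = theta[2, ],
                 neck_angles = neck_ang, torso_base = B, head_base = J,
                 head_cog = traj$position, d = d, flagged = flagged,
                 dt = traj$dt, params = params),
            class = "neck_trajectory")
}

SIGNMATCH_DEADBAND_RAD <- 1e-3
RATIO_DEADBAND_G <- 0.5

#' Linkage-model feature sub-block (33 features)
#'
#' Non-ratio model features from a solved neck trajectory: percent of the
#' window during which each head-neck universal angle matches sign with the
#' same-plane neck orientation angle (a continuous cervical rotation
#' indicator; angles within a 1e-3 rad deadband match either sign, so a
#' stationary trajectory scores 100%); peak absolute joint angles, angular
#' velocities, and angular accelerations of the five angle series; peak
#' displacement, velocity and acceleration magnitudes of the torso-base,
#' head-base, and head-CoG points (displacement relative to t = 0); peak
#' per-axis head-CoG displacement and velocity; and the peak torso-base
#' offset d.
#'
#' @param nmt A `neck_trajectory` from [solve_linkage()].
#' @return Named numeric vector of 33 features.
#' @export
neck_model_trajectory_features <- function(nmt) {
  dt <- nmt$dt
  sign_match <- function(a, b) {
    match <- abs(a) < SIGNMATCH_DEADBAND_RAD |
      abs(b) < SIGNMATCH_DEADBAND_RAD | sign(a) == sign(b)
    100 * mean(match)
  }
  angles <- rbind(nmt$theta_lr, nmt$theta_is, nmt$neck_angles)
  angvel <- t(apply(angles, 1, five_point_derivative, dt = dt))
  angacc <- t(apply(angvel, 1, five_point_derivative, dt = dt))
  point_feats <- function(P) {
    disp <- sqrt(colSums((P - P[, 1])^2))
    vel <- t(apply(P, 1, five_point_derivative, dt = dt))
    acc <- t(apply(vel, 1, five_point_derivative, dt = dt))
    c(max(disp), max(sqrt(colSums(vel^2))), max(sqrt(colSums(acc^2))))
  }
  cog_disp <- abs(nmt$head_cog - nmt$head_cog[, 1])
  cog_vel <- t(apply(nmt$head_cog, 1, five_point_derivative, dt = dt))
  vals <- c(
    sign_match(nmt$theta_lr, nmt$neck_angles[2, ]),
    sign_match(nmt$theta_is, nmt$neck_angles[3, ]),
    apply(abs(angles), 1, max),
    apply(abs(angvel), 1, max),
    apply(abs(angacc), 1, max),
    point_feats(nmt$torso_base), point_feats(nmt$head_base),
    point_feats(nmt$head_cog),
    apply(cog_disp, 1, max),
    apply(abs(cog_vel), 1, max),
    max(nmt$d)
  )
  reg <- feature_registry()
  stats::setNames(vals, reg[360 + seq_len(33)])
}

#' Angular/linear acceleration coupling-ratio statistics (18 features)
#'
#' The neck couples angular and linear head motion, so their ratio carries
#' biomechanical information. For each anatomical rotation axis the angular
#' acceleration is divided, sample by sample, by the linear acceleration
#' along each of the two normal directions (six ratio series: coronal/LR,
#' coronal/IS, sagittal/AP, sagittal/IS, horizontal/AP, horizontal/LR);
#' mean, standard deviation, and peak absolute value of each series are the
#' features. Samples whose linear-acceleration denominator is below 0.5 g
#' are excluded; if every sample is excluded, the three statistics are 0
#' (flagged). Ratio units: (rad/s^2) / g.
#'
#' @param sig An `anatomical_signals` object.
#' @return Named numeric vector of 18 features.
#' @export
coupling_ratios <- function(sig) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  vals <- numeric(0)
  degenerate <- FALSE
  for (p in pairs) {
    num <- sig$ang_acc[p[1], ]
    den <- sig$lin_acc[p[2], ]
    keep <- abs(den) >= RATIO_DEADBAND_G
    if (!any(keep)) {
      vals <- c(vals, 0, 0, 0)
      degenerate <- TRUE
    } else {
      r <- num[keep] / den[keep]
      vals <- c(vals, mean(r), if (sum(keep) > 1) stats::sd(r) else 0,
                max(abs(r)))
    }
  }
  reg <- feature_registry()
  structure(stats::setNames(vals, reg[393 + seq_len(18)]),
            degenerate = degenerate)
}

#' Full linkage-model feature block (51 features)
#'
#' Integrates the head pose, solves the linkage, and returns the 33
#' trajectory features plus the 18 coupling-ratio statistics.
#'
#' @param sig An `anatomical_signals` object.
#' @param params A [neck_model_params()].
#' @return Named numeric vector of 51 features.
#' @export
neck_model_features_from_signals <- function(sig, params = neck_model_params()) {
  traj <- integrate_head_pose(sig, params)
  nmt <- solve_linkage(traj, params)
  out <- c(neck_model_trajectory_features(nmt),
           as.numeric(coupling_ratios(sig)))
  reg <- feature_registry()
  stats::setNames(out, reg[360 + seq_len(51)])
}

#' @rdname neck_model_trajectory_features
#' @param ... Passed through.
#' @export
neck_model_features <- function(nmt, ...) neck_model_trajectory_features(nmt)
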