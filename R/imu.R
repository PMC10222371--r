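# Head-IMU processing: attitude estimation and gravity-compensated
# horizontal acceleration.
#
# The accelerometer measures specific force (acceleration minus gravity,
# expressed in the sensor frame), so recovering horizontal head acceleration
# needs the sensor attitude.  Attitude is estimated by an error-state
# extended Kalman filter: the nominal quaternion is propagated by gyro
# integration and a gravity-direction measurement update corrects tilt and
# estimates a slowly varying gyro bias.  The measurement gain is kept
# deliberately low (the accelerometer direction is a poor attitude reference
# while the head accelerates), so the filter behaves like a
# gyro-dominated complementary filter with a crossover well below the
# postural-sway band; a quiescent lead-in segment provides the initial tilt
# and gravity magnitude.  Yaw is unobservable without a magnetometer and is
# irrelevant here: only the two horizontal components are used.

quat_mult <- function(q, r) {
  c(q[1] * r[1] - q[2] * r[2] - q[3] * r[3] - q[4] * r[4],
    q[1] * r[2] + q[2] * r[1] + q[3] * r[4] - q[4] * r[3],
    q[1] * r[3] - q[2] * r[4] + q[3] * r[1] + q[4] * r[2],
    q[1] * r[4] + q[2] * r[3] - q[3] * r[2] + q[4] * r[1])
}

quat_from_rotvec <- function(v) {
  a <- sqrt(sum(v^2))
  if (a < 1e-12) return(c(1, v / 2))
  c(cos(a / 2), sin(a / 2) * v / a)
}

# body-to-world rotation matrix from a unit quaternion
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

skew <- function(v) matrix(c(0, v[3], -v[2],
                             -v[3], 0, v[1],
                             v[2], -v[1], 0), 3, 3)

# initial tilt quaternion from the mean specific force of a quiescent
# segment: rotate so that f maps onto +z (no yaw)
tilt_from_accel <- function(f) {
  fhat <- f / sqrt(sum(f^2))
  z <- c(0, 0, 1)
  axis <- c(fhat[2] * 1 - fhat[3] * 0,          # fhat x z
            fhat[3] * 0 - fhat[1] * 1,
            0)
  sa <- sqrt(sum(axis^2))
  ang <- atan2(sa, fhat[3])
  if (sa < 1e-12) return(c(1, 0, 0, 0))
  quat_from_rotvec(axis / sa * ang)
}

#' Horizontal head acceleration from raw IMU channels
#'
#' Estimates the sensor attitude with a quaternion error-state EKF (tilt +
#' gyro bias), rotates the specific force into the stationary frame,
#' removes gravity and returns the two horizontal acceleration components.
#' The gravity magnitude and initial tilt are taken from the first
#' `init_window` seconds, which must be quiescent.
#'
#' @param imu data frame with columns `t, ax, ay, az` (specific force,
#'   m/s^2) and `gx, gy, gz` (angular rate, rad/s).
#' @param fs sampling frequency, Hz.
#' @param init_window quiescent lead-in used for initialization, s.
#' @param gyro_sd gyro white-noise SD assumed by the filter, rad/s.
#' @param accel_dir_sd accelerometer direction noise assumed by the filter,
#'   m/s^2; large values make the filter trust the gyro more.
#' @param bias_rw_sd gyro-bias random-walk SD, rad/s per sqrt(s).
#' @param gate_frac measurement updates are de-weighted (noise inflated
#'   100-fold) whenever the specific-force norm deviates from gravity by
#'   more than this fraction.
#' @return data frame `t, Xhdd, Yhdd` (stationary-frame horizontal head
#'   acceleration, m/s^2); the attitude quaternion history is attached as
#'   attribute `"quaternion"`.
#' @export
imu_horizontal_acceleration <- function(imu, fs, init_window = 1,
                                        gyro_sd = 0.002,
                                        accel_dir_sd = 2.0,
                                        bias_rw_sd = 1e-5,
                                        gate_frac = 0.03) {
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(imu))
  if (length(miss))
    stop("IMU stream lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(imu)
  dt <- 1 / fs
  acc <- as.matrix(imu[, c("ax", "ay", "az")])
  gyr <- as.matrix(imu[, c("gx", "gy", "gz")])
  norms <- sqrt(rowSums(acc^2))
  i0 <- which(imu$t <= init_window)
  ghat <- mean(norms[i0])
  if (stats::median(norms) < 0.5 * ghat || stats::median(norms) > 1.5 * ghat
      || ghat < 4.9 || ghat > 19.6)
    stop("specific-force norm inconsistent with gravity; ",
         "attitude estimation unreliable", call. = FALSE)

  q <- tilt_from_accel(colMeans(acc[i0, , drop = FALSE]))
  bias <- colMeans(gyr[i0, , drop = FALSE])
  # lead-in averaging makes the initial tilt/bias accurate to ~1 mrad, so
  # the prior is tight; an inflated prior would keep the gravity gain high
  # for most of a 40 s record and leak horizontal acceleration into tilt
  P <- diag(c(rep(1e-6, 3), rep(1e-8, 3)))
  Qd <- diag(c(rep((gyro_sd * dt)^2, 3), rep(bias_rw_sd^2 * dt, 3)))
  r0 <- (accel_dir_sd / ghat)^2

  out <- matrix(0, n, 2)
  qs <- matrix(0, n, 4)
  for (k in seq_len(n)) {
    if (k > 1) {
      w <- gyr[k, ] - bias
      q <- quat_mult(q, quat_from_rotvec(w * dt))
      q <- q / sqrt(sum(q^2))
      Fk <- rbind(cbind(diag(3) - skew(w * dt), -dt * diag(3)),
                  cbind(matrix(0, 3, 3), diag(3)))
      P <- Fk %*% P %*% t(Fk) + Qd
    }
    R <- quat_to_matrix(q)
    gb <- as.numeric(t(R) %*% c(0, 0, 1))       # gravity direction in body
    fhat <- acc[k, ] / norms[k]
    r <- if (abs(norms[k] - ghat) > gate_frac * ghat) 100 * r0 else r0
    H <- cbind(skew(gb), matrix(0, 3, 3))
    S <- H %*% P %*% t(H) + r * diag(3)
    K <- P %*% t(H) %*% solve(S)
    dx <- as.numeric(K %*% (fhat - gb))
    q <- quat_mult(q, quat_from_rotvec(dx[1:3]))
    q <- q / sqrt(sum(q^2))
    bias <- bias + dx[4:6]
    P <- (diag(6) - K %*% H) %*% P
    P <- (P + t(P)) / 2
    R <- quat_to_matrix(q)
    aw <- as.numeric(R %*% acc[k, ]) - c(0, 0, ghat)
    out[k, ] <- aw[1:2]
    qs[k, ] <- q
  }
  res <- data.frame(t = imu$t, Xhdd = out[, 1], Yhdd = out[, 2])
  attr(res, "quaternion") <- qs
  res
}
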