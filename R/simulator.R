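# Synthetic standing trials with ground truth.
#
# Six motion conditions are emulated: quiet standing, voluntary
# ankle-strategy sway in the sagittal (AP) and frontal (ML) planes at
# 0.25 Hz, voluntary hip-strategy motion (AP) at 1 Hz, and horizontal
# support-surface sway (AP, ML) driven by a 20-harmonic waveform.
# Trajectories are prescribed (open loop; no balance controller), converted
# to sensor signals either by linear inverse dynamics that evaluates the
# same small-angle equations the estimators invert (written as a separate
# code path), or by the exact nonlinear Newton-Euler oracle in oracle.R.

#' Motion specification for the trial generator
#'
#' @param motion one of `"quiet"`, `"ankle_AP"`, `"ankle_ML"`, `"hip_AP"`,
#'   `"sway_AP"`, `"sway_ML"`.
#' @param amplitude voluntary-motion amplitude: joint angle in rad for ankle
#'   and hip motions, support-displacement RMS in m for sway motions.
#'   Defaults: 0.03 rad (ankle), 0.01 rad (hip, lower-body angle),
#'   0.01 m (sway); ignored for quiet standing.
#' @param frequency voluntary-motion frequency in Hz (default 0.25 for ankle,
#'   1 for hip; sway uses its fixed 20-harmonic set).
#' @param duration trial length, s (default 40).
#' @param fs sampling frequency, Hz (default 100).
#' @param seed integer seed controlling every random component.
#' @param background logical; superimpose quiet-standing background sway on
#'   voluntary motions (default TRUE).  Humans never hold a voluntary
#'   oscillation without residual postural sway, and the background is what
#'   keeps the synthetic hip trial from being a single pure sinusoid.
#' @param background_rms RMS of the common (whole-body) background sway
#'   angle, rad (default 0.003; band 0.05-1 Hz).
#' @param background_upper_rms RMS of an additional independent upper-body
#'   angle component, rad (default 0.0015; band 0.1-2 Hz).  Quiet stance is
#'   not a pure single pendulum -- a small, faster hip component rides on
#'   the ankle sway -- and this component is what gives the head sensor
#'   genuine information even in quiet standing.
#' @param hip_ratio upper-body to lower-body counter-rotation ratio of the
#'   hip strategy (default 2: the trunk rotates twice as far as the legs,
#'   in anti-phase, which keeps the COM excursion at the few-millimetre
#'   level while segment accelerations are large).
#' @return object of class `"motion_spec"`.
#' @export
motion_spec <- function(motion = c("quiet", "ankle_AP", "ankle_ML", "hip_AP",
                                   "sway_AP", "sway_ML"),
                        amplitude = NULL, frequency = NULL,
                        duration = 40, fs = 100, seed = 1L,
                        background = TRUE, background_rms = 0.003,
                        background_upper_rms = 0.0015, hip_ratio = 2) {
  motion <- match.arg(motion)
  if (abs(duration * fs - round(duration * fs)) > 1e-9)
    stop("duration * fs must be an integer number of samples", call. = FALSE)
  if (is.null(frequency))
    frequency <- switch(motion, ankle_AP = 0.25, ankle_ML = 0.25,
                        hip_AP = 1, 0)
  if (is.null(amplitude))
    amplitude <- switch(motion,
                        ankle_AP = 0.03, ankle_ML = 0.03,
                        hip_AP = 0.01,
                        sway_AP = 0.01, sway_ML = 0.01,
                        quiet = 0)
  if (motion %in% c("ankle_AP", "ankle_ML", "hip_AP") && amplitude > 0.05)
    stop("joint amplitude ", amplitude,
         " rad exceeds the small-angle validity bound (0.05 rad)",
         call. = FALSE)
  structure(list(motion = motion, amplitude = amplitude,
                 frequency = frequency, duration = duration, fs = fs,
                 seed = as.integer(seed), background = background,
                 background_rms = background_rms,
                 background_upper_rms = background_upper_rms,
                 hip_ratio = hip_ratio),
            class = "motion_spec")
}

#' Support-surface excitation waveform
#'
#' Superposition of 20 harmonic components at 0.05, 0.10, ..., 1.00 Hz with
#' equal displacement amplitudes and seed-determined uniform random phases,
#' scaled so the displacement RMS equals `rms_amplitude`.  Velocity and
#' acceleration are returned analytically.
#'
#' @param duration length, s.
#' @param fs sampling frequency, Hz (> 2).
#' @param rms_amplitude target displacement RMS, m.
#' @param seed integer seed for the phases.
#' @return data.frame with `t`, `x` (m), `xd` (m/s), `xdd` (m/s^2).
#' @export
sway_waveform <- function(duration, fs, rms_amplitude, seed = 1L) {
  if (fs <= 2) stop("'fs' must exceed 2 Hz", call. = FALSE)
  t <- seq(0, duration, by = 1 / fs)
  fk <- seq(0.05, 1.00, by = 0.05)
  set.seed(seed)
  ph <- runif(20, 0, 2 * pi)
  A <- rms_amplitude / sqrt(10)   # 20 equal sinusoids: rms = A*sqrt(20/2)
  x <- xd <- xdd <- numeric(length(t))
  for (k in seq_along(fk)) {
    w <- 2 * pi * fk[k]
    x <- x + A * sin(w * t + ph[k])
    xd <- xd + A * w * cos(w * t + ph[k])
    xdd <- xdd - A * w^2 * sin(w * t + ph[k])
  }
  data.frame(t = t, x = x, xd = xd, xdd = xdd)
}

# Smooth taper window with analytic first/second derivatives: exactly zero
# for the first `lead` seconds (a quiescent hold that gives IMU attitude
# initialization a rest segment), rising over `ramp` seconds, and falling
# back to zero at the record end.  A quintic smoothstep is used so that the
# window -- and hence every generated acceleration -- is C^3: trajectories
# must not inject low-order derivative kinks that numerical-differentiation
# audits would see.
taper_window <- function(t, ramp = 2, lead = 1) {
  T <- max(t)
  w <- rep(1, length(t)); wd <- wdd <- numeric(length(t))
  smooth5 <- function(s) list(
    w = 35 * s^4 - 84 * s^5 + 70 * s^6 - 20 * s^7,
    wd = 140 * s^3 - 420 * s^4 + 420 * s^5 - 140 * s^6,
    wdd = 420 * s^2 - 1680 * s^3 + 2100 * s^4 - 840 * s^5)
  hold <- t < lead
  up <- t >= lead & t < lead + ramp
  dn <- t > T - ramp
  w[hold] <- 0
  su <- smooth5((t[up] - lead) / ramp)
  w[up] <- su$w; wd[up] <- su$wd / ramp; wdd[up] <- su$wdd / ramp^2
  sd <- smooth5((T - t[dn]) / ramp)
  w[dn] <- sd$w; wd[dn] <- -sd$wd / ramp; wdd[dn] <- sd$wdd / ramp^2
  list(w = w, wd = wd, wdd = wdd)
}

# Multiply a series (with analytic derivatives) by the taper window,
# propagating derivatives: (wx)'' = w''x + 2w'x' + wx''.
apply_taper <- function(x, xd, xdd, win) {
  list(x = win$w * x,
       xd = win$wd * x + win$w * xd,
       xdd = win$wdd * x + 2 * win$wd * xd + win$w * xdd)
}

# Random-phase multisine with 1/f amplitude weighting, scaled to a target
# RMS: a band-limited surrogate for postural-sway angle noise.
# Returns x, xd, xdd (analytic).
quiet_multisine <- function(t, rms, fmin = 0.05, fmax = 1.00, df = 0.05) {
  fk <- seq(fmin, fmax, by = df)
  a <- 1 / fk
  a <- a * rms / sqrt(sum(a^2 / 2))
  ph <- runif(length(fk), 0, 2 * pi)
  x <- xd <- xdd <- numeric(length(t))
  for (k in seq_along(fk)) {
    w <- 2 * pi * fk[k]
    x <- x + a[k] * sin(w * t + ph[k])
    xd <- xd + a[k] * w * cos(w * t + ph[k])
    xdd <- xdd - a[k] * w^2 * sin(w * t + ph[k])
  }
  list(x = x, xd = xd, xdd = xdd)
}

zero_series <- function(t) list(x = numeric(length(t)),
                                xd = numeric(length(t)),
                                xdd = numeric(length(t)))

#' Generate ground-truth joint trajectories
#'
#' Builds the angle trajectories (and support motion) for one motion
#' condition.  Ankle motions set equal lower/upper angles (single-pendulum
#' kinematics); hip motion sets counter-phase angles with the upper body
#' rotating `hip_ratio` times as far as the lower body; quiet standing is a
#' seeded band-limited (0.05-1 Hz) random sway angle; sway motions combine a
#' quiet-standing angle background with the 20-harmonic support waveform.
#' Voluntary and background components are smoothly tapered to zero over the
#' first and last 2 s.  All derivatives are analytic.
#'
#' @param spec a [motion_spec()].
#' @return object of class `"com_truth"` with components `sagittal` and
#'   `frontal` (data frames `t, th1, th1d, th1dd, th2, th2d, th2dd`),
#'   `support` (data frame `t, Xs, Xsd, Xsdd, Ys, Ysd, Ysdd`), and fields
#'   `fs`, `motion`, `spec`.  Angles only; see [truth_kinematics()].
#' @export
make_trajectories <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$fs)
  win <- taper_window(t)
  set.seed(spec$seed)

  bg_on <- spec$background || spec$motion == "quiet"
  bg_sag <- if (bg_on) quiet_multisine(t, spec$background_rms)
            else zero_series(t)
  bg_sag_up <- if (bg_on)
    quiet_multisine(t, spec$background_upper_rms, fmin = 0.1, fmax = 2,
                    df = 0.1) else zero_series(t)
  bg_fro <- if (bg_on) quiet_multisine(t, spec$background_rms)
            else zero_series(t)
  bg_fro_up <- if (bg_on)
    quiet_multisine(t, spec$background_upper_rms, fmin = 0.1, fmax = 2,
                    df = 0.1) else zero_series(t)

  sinus <- function(a, f) {
    w <- 2 * pi * f
    list(x = a * sin(w * t), xd = a * w * cos(w * t),
         xdd = -a * w^2 * sin(w * t))
  }
  zero <- zero_series(t)
  vol_sag1 <- vol_sag2 <- vol_fro <- zero
  sup_x <- sup_y <- zero

  if (spec$motion %in% c("ankle_AP")) {
    vol_sag1 <- vol_sag2 <- sinus(spec$amplitude, spec$frequency)
  } else if (spec$motion == "hip_AP") {
    vol_sag1 <- sinus(spec$amplitude, spec$frequency)
    vol_sag2 <- sinus(-spec$hip_ratio * spec$amplitude, spec$frequency)
  } else if (spec$motion == "ankle_ML") {
    vol_fro <- sinus(spec$amplitude, spec$frequency)
  } else if (spec$motion %in% c("sway_AP", "sway_ML")) {
    sw <- sway_waveform(spec$duration, spec$fs, spec$amplitude,
                        seed = spec$seed + 1L)
    sw <- list(x = sw$x, xd = sw$xd, xdd = sw$xdd)
    if (spec$motion == "sway_AP") sup_x <- sw else sup_y <- sw
  }

  add3 <- function(...) {
    parts <- list(...)
    Reduce(function(a, b) list(x = a$x + b$x, xd = a$xd + b$xd,
                               xdd = a$xdd + b$xdd), parts)
  }
  tap <- function(s) apply_taper(s$x, s$xd, s$xdd, win)
  th1 <- tap(add3(vol_sag1, bg_sag))
  th2 <- tap(add3(vol_sag2, bg_sag, bg_sag_up))
  thl <- tap(add3(vol_fro, bg_fro))
  thu <- tap(add3(vol_fro, bg_fro, bg_fro_up))
  supx <- tap(sup_x)
  supy <- tap(sup_y)

  structure(list(
    sagittal = data.frame(t = t, th1 = th1$x, th1d = th1$xd, th1dd = th1$xdd,
                          th2 = th2$x, th2d = th2$xd, th2dd = th2$xdd),
    frontal = data.frame(t = t, th1 = thl$x, th1d = thl$xd, th1dd = thl$xdd,
                         th2 = thu$x, th2d = thu$xd, th2dd = thu$xdd),
    support = data.frame(t = t, Xs = supx$x, Xsd = supx$xd, Xsdd = supx$xdd,
                         Ys = supy$x, Ysd = supy$xd, Ysdd = supy$xdd),
    fs = spec$fs, motion = spec$motion, spec = spec
  ), class = "com_truth")
}

#' Derive COM kinematics from joint trajectories
#'
#' Fills in segment and whole-body COM displacement series (moving frame)
#' and the head-point kinematics implied by the small-angle geometry.
#' With `model = "double"` the sagittal COM lever follows the two-segment
#' composition `x_b = (m_1 x_1 + m_2 x_2)/m_b` (frontal: leg/pelvis/upper
#' composition); with `model = "single"` the tabulated whole-body lever
#' `l_b` is used directly, which makes the trajectories exactly consistent
#' with the single-pendulum equations (the tabulated `l_b` and the
#' composite lever differ by the rounding of the regression coefficients).
#'
#' @param truth output of [make_trajectories()].
#' @param params a [segment_parameters()] set.
#' @param model `"double"` (default) or `"single"`.
#' @return `truth` with per-plane columns `x1, x2, xb, xbd, xbdd, x1dd,
#'   x2dd, xh, xhdd` added (for the frontal plane, x1/x2 are the leg and
#'   upper-body COM series and the pelvis follows the hip point).
#' @export
truth_kinematics <- function(truth, params, model = c("double", "single")) {
  model <- match.arg(model)
  stopifnot(inherits(truth, "com_truth"),
            inherits(params, "segment_params"))
  s <- as.list(params$sagittal); f <- as.list(params$frontal)

  fill <- function(d, lev1, lev21, lev22, wb1, wb21, wb22, lb,
                   hl1, hl2) {
    # segment COM displacements: x1 = lev1*th1 ; x2 = lev21*th1 + lev22*th2
    d$x1 <- lev1 * d$th1
    d$x1d <- lev1 * d$th1d
    d$x1dd <- lev1 * d$th1dd
    d$x2 <- lev21 * d$th1 + lev22 * d$th2
    d$x2d <- lev21 * d$th1d + lev22 * d$th2d
    d$x2dd <- lev21 * d$th1dd + lev22 * d$th2dd
    if (model == "single") {
      d$xb <- lb * d$th1; d$xbd <- lb * d$th1d; d$xbdd <- lb * d$th1dd
    } else {
      d$xb <- wb1 * d$x1 + wb21 * d$th1 + wb22 * d$th2
      d$xbd <- wb1 * d$x1d + wb21 * d$th1d + wb22 * d$th2d
      d$xbdd <- wb1 * d$x1dd + wb21 * d$th1dd + wb22 * d$th2dd
    }
    d$xh <- hl1 * d$th1 + hl2 * d$th2
    d$xhd <- hl1 * d$th1d + hl2 * d$th2d
    d$xhdd <- hl1 * d$th1dd + hl2 * d$th2dd
    d
  }

  m_b <- s$m_b
  # sagittal: xb = (m1 x1 + m2 x2)/mb ; x2 = L1 th1 + l2 th2
  truth$sagittal <- fill(truth$sagittal,
    lev1 = s$l_1, lev21 = s$L_1, lev22 = s$l_2,
    wb1 = s$m_1 / m_b, wb21 = s$m_2 * s$L_1 / m_b, wb22 = s$m_2 * s$l_2 / m_b,
    lb = s$l_b, hl1 = s$L_1, hl2 = s$L_2)
  # frontal: legs rotate (lever l_l), pelvis translates with the hip
  # (lever L_l), upper body adds l_u about the waist:
  # yb = (2 m_l y_l + m_p L_l th + m_u (L_l th + l_u thu))/m_b
  truth$frontal <- fill(truth$frontal,
    lev1 = f$l_l, lev21 = f$L_l, lev22 = f$l_u,
    wb1 = 2 * f$m_l / m_b,
    wb21 = (f$m_p + f$m_u) * f$L_l / m_b,
    wb22 = f$m_u * f$l_u / m_b,
    lb = s$l_b, hl1 = f$L_l, hl2 = f$L_u)
  truth$model <- model
  truth
}

#' Linear inverse dynamics: trajectories to sensor signals
#'
#' Substitutes the ground-truth kinematics into the linearized equations of
#' motion to produce the force-platform channels, head acceleration and
#' support motion that a trial with those trajectories would record.  This
#' is the forward evaluation of exactly the model forms the estimators
#' invert (kept as an independent code path); the vertical force is the
#' static weight `M g`.
#'
#' @param truth a [truth_kinematics()]-completed `com_truth`.
#' @param params segment parameters.
#' @param inertias matching [composite_inertias()].
#' @return list with `plate` (`t, Rx, Ry, Fz, Nx, Ny`), `head`
#'   (`t, Xhdd, Yhdd`, stationary frame) and `support` (`t, Xsdd, Ysdd`)
#'   data frames.
#' @export
inverse_dynamics_linear <- function(truth, params, inertias) {
  stopifnot(inherits(truth, "com_truth"))
  if (is.null(truth$model))
    stop("run truth_kinematics() before inverse dynamics", call. = FALSE)
  s <- as.list(params$sagittal); f <- as.list(params$frontal)
  ci <- inertias
  subj <- params$subject
  M <- subj$M; g <- subj$g
  sg <- truth$sagittal; fr <- truth$frontal; sup <- truth$support
  lever_s <- M * (s$L_f + s$l_b)

  if (truth$model == "single") {
    Rx <- -M * sup$Xsdd - s$m_b * sg$xbdd
    Ny <- -lever_s * sup$Xsdd - (ci$C_sag * sg$xbdd - s$m_b * g * sg$xb)
    Ry <- -M * sup$Ysdd - s$m_b * fr$xbdd
    Nx <- ci$J_yb * fr$xbdd - s$m_b * g * fr$xb + lever_s * sup$Ysdd
  } else {
    Rx <- -M * sup$Xsdd - (s$m_1 * sg$x1dd + s$m_2 * sg$x2dd)
    Ny <- -lever_s * sup$Xsdd -
      (ci$J_x1 * sg$x1dd + ci$J_x2 * sg$x2dd - s$m_b * g * sg$xb)
    Ry <- -M * sup$Ysdd -
      ((2 * f$m_l + f$m_p * f$L_l / f$l_l) * fr$x1dd + f$m_u * fr$x2dd)
    Nx <- ci$J_y1 * fr$x1dd + ci$J_y2 * fr$x2dd - s$m_b * g * fr$xb +
      lever_s * sup$Ysdd
  }
  Fz <- rep(M * g, nrow(sg))
  list(
    plate = data.frame(t = sg$t, Rx = Rx, Ry = Ry, Fz = Fz, Nx = Nx, Ny = Ny),
    head = data.frame(t = sg$t, Xhdd = sg$xhdd + sup$Xsdd,
                      Yhdd = fr$xhdd + sup$Ysdd),
    support = data.frame(t = sg$t, Xsdd = sup$Xsdd, Ysdd = sup$Ysdd)
  )
}

#' Sensor-noise specification
#'
#' @param force_sd white-noise SD on horizontal forces Rx, Ry (N).
#' @param moment_sd white-noise SD on moments Nx, Ny (N m).
#' @param fz_sd white-noise SD on the vertical force (N).
#' @param head_acc_sd white-noise SD on head-acceleration channels (m/s^2)
#'   -- applied to a direct head-acceleration stream.
#' @param imu_acc_sd white-noise SD on raw IMU specific-force axes (m/s^2).
#' @param imu_gyro_sd white-noise SD on raw IMU rate axes (rad/s).
#' @param support_sd white-noise SD on support-acceleration channels (m/s^2).
#' @param force_drift_rate deterministic ramp added to Rx and Ry (N/s).
#' @param head_sync_offset delay applied to the head stream only, s
#'   (positive = head stream lags the platform).
#' @param seed integer seed.
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(force_sd = 0.1, moment_sd = 0.05, fz_sd = 0.5,
                       head_acc_sd = 0.02, imu_acc_sd = 0.02,
                       imu_gyro_sd = 0.002, support_sd = 0.005,
                       force_drift_rate = 0, head_sync_offset = 0,
                       seed = 1L) {
  vals <- c(force_sd, moment_sd, fz_sd, head_acc_sd, imu_acc_sd,
            imu_gyro_sd, support_sd)
  if (any(vals < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(force_sd = force_sd, moment_sd = moment_sd, fz_sd = fz_sd,
                 head_acc_sd = head_acc_sd, imu_acc_sd = imu_acc_sd,
                 imu_gyro_sd = imu_gyro_sd, support_sd = support_sd,
                 force_drift_rate = force_drift_rate,
                 head_sync_offset = head_sync_offset,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# delay a series by `offset` seconds (fractional allowed) via linear
# interpolation, holding the first value over the lead-in
delay_series <- function(x, t, offset) {
  if (offset == 0) return(x)
  approx(t, x, xout = t - offset, rule = 2)$y
}

#' Add sensor noise to a simulated trial
#'
#' Applies seeded Gaussian noise per channel, an optional deterministic
#' drift ramp on the horizontal forces, and an optional synchronization
#' offset on the head stream (IMU channels and/or direct head acceleration).
#' With an all-zero spec the trial is returned bit-identically.
#'
#' @param trial a `com_trial` from [simulate_trial()].
#' @param spec a [noise_spec()].
#' @return the trial with noisy sensor streams; `trial$noise` records the
#'   spec.  Ground truth is untouched.
#' @export
add_noise <- function(trial, spec) {
  stopifnot(inherits(trial, "com_trial"), inherits(spec, "noise_spec"))
  set.seed(spec$seed)
  n <- nrow(trial$plate)
  t <- trial$plate$t
  pl <- trial$plate
  if (spec$force_sd > 0) {
    pl$Rx <- pl$Rx + rnorm(n, 0, spec$force_sd)
    pl$Ry <- pl$Ry + rnorm(n, 0, spec$force_sd)
  }
  if (spec$moment_sd > 0) {
    pl$Nx <- pl$Nx + rnorm(n, 0, spec$moment_sd)
    pl$Ny <- pl$Ny + rnorm(n, 0, spec$moment_sd)
  }
  if (spec$fz_sd > 0) pl$Fz <- pl$Fz + rnorm(n, 0, spec$fz_sd)
  if (spec$force_drift_rate != 0) {
    pl$Rx <- pl$Rx + spec$force_drift_rate * t
    pl$Ry <- pl$Ry + spec$force_drift_rate * t
  }
  trial$plate <- pl
  if (!is.null(trial$support) && spec$support_sd > 0) {
    trial$support$Xsdd <- trial$support$Xsdd + rnorm(n, 0, spec$support_sd)
    trial$support$Ysdd <- trial$support$Ysdd + rnorm(n, 0, spec$support_sd)
  }
  if (!is.null(trial$head)) {
    h <- trial$head
    if (spec$head_sync_offset != 0) {
      h$Xhdd <- delay_series(h$Xhdd, t, spec$head_sync_offset)
      h$Yhdd <- delay_series(h$Yhdd, t, spec$head_sync_offset)
    }
    if (spec$head_acc_sd > 0) {
      h$Xhdd <- h$Xhdd + rnorm(n, 0, spec$head_acc_sd)
      h$Yhdd <- h$Yhdd + rnorm(n, 0, spec$head_acc_sd)
    }
    trial$head <- h
  }
  if (!is.null(trial$imu)) {
    im <- trial$imu
    if (spec$head_sync_offset != 0)
      for (nm in c("ax", "ay", "az", "gx", "gy", "gz"))
        im[[nm]] <- delay_series(im[[nm]], t, spec$head_sync_offset)
    if (spec$imu_acc_sd > 0)
      for (nm in c("ax", "ay", "az"))
        im[[nm]] <- im[[nm]] + rnorm(n, 0, spec$imu_acc_sd)
    if (spec$imu_gyro_sd > 0)
      for (nm in c("gx", "gy", "gz"))
        im[[nm]] <- im[[nm]] + rnorm(n, 0, spec$imu_gyro_sd)
    trial$imu <- im
  }
  trial$noise <- spec
  trial
}

#' Simulate a complete standing trial
#'
#' Generates trajectories for a motion condition, runs inverse dynamics
#' (linear model forms, or the exact nonlinear Newton-Euler oracle), and
#' bundles sensor streams, subject and ground truth into a trial object.
#'
#' With `oracle = "linear"` both planes are populated (voluntary motion in
#' its plane, background sway in both) and the head stream is the model's
#' head acceleration.  With `oracle = "nonlinear"` the trial is strictly
#' planar: the requested plane carries the motion, the other plane's
#' channels are zero, and the head stream contains both ideal IMU channels
#' and the exact head acceleration.
#'
#' @param motion motion tag or a full [motion_spec()].
#' @param subject a [com_subject()] (default 70 kg, 1.75 m).
#' @param noise optional [noise_spec()].
#' @param oracle `"linear"` (default) or `"nonlinear"`.
#' @param model generating model for the linear oracle: `"double"` (full
#'   two-segment / leg-pelvis-trunk forms, default) or `"single"`
#'   (whole-body pendulum forms).
#' @param plane plane of a nonlinear trial (`"sagittal"` or `"frontal"`).
#' @param seed integer seed (forwarded to the spec when `motion` is a tag).
#' @param ... further arguments to [motion_spec()].
#' @return object of class `"com_trial"`.
#' @export
simulate_trial <- function(motion, subject = com_subject(70, 1.75),
                           noise = NULL, oracle = c("linear", "nonlinear"),
                           model = c("double", "single"),
                           plane = c("sagittal", "frontal"),
                           seed = 1L, ...) {
  oracle <- match.arg(oracle)
  model <- match.arg(model)
  plane <- match.arg(plane)
  spec <- if (inherits(motion, "motion_spec")) motion
          else motion_spec(motion, seed = seed, ...)
  params <- segment_parameters(subject)
  inert <- composite_inertias(params)
  truth <- make_trajectories(spec)

  if (oracle == "linear") {
    truth <- truth_kinematics(truth, params, model = model)
    sig <- inverse_dynamics_linear(truth, params, inert)
    trial <- structure(list(plate = sig$plate, head = sig$head, imu = NULL,
                            support = sig$support, subject = subject,
                            fs = spec$fs, motion = spec$motion,
                            truth = truth, oracle = "linear", model = model,
                            seed = spec$seed),
                       class = "com_trial")
  } else {
    sig <- inverse_dynamics_nonlinear(truth, params, plane = plane)
    trial <- structure(list(plate = sig$plate, head = sig$head,
                            imu = sig$imu, support = sig$support,
                            subject = subject, fs = spec$fs,
                            motion = spec$motion, truth = sig$truth,
                            oracle = "nonlinear", model = "nonlinear",
                            plane = plane, seed = spec$seed),
                       class = "com_trial")
  }
  if (!is.null(noise)) trial <- add_noise(trial, noise)
  trial
}

#' @export
print.com_trial <- function(x, ...) {
  cat(sprintf("Standing trial: %s (%s dynamics%s), %.0f s @ %g Hz\n",
              x$motion, x$oracle,
              if (x$oracle == "linear") paste0(", ", x$model, " model")
              else paste0(", ", x$plane, " plane"),
              max(x$plate$t), x$fs))
  cat(sprintf("  subject M = %.1f kg, H = %.2f m; seed %d; %s\n",
              x$subject$M, x$subject$H, x$seed,
              if (is.null(x$noise)) "noise-free" else "with sensor noise"))
  cat("  streams: plate",
      if (!is.null(x$head)) "+ head acceleration",
      if (!is.null(x$imu)) "+ IMU",
      "+ support\n")
  invisible(x)
}

#' @export
plot.com_trial <- function(x, ...) {
  op <- par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(par(op))
  plot(x$plate$t, x$plate$Rx, type = "l", xlab = "", ylab = "Rx, Ry [N]",
       main = paste("trial:", x$motion))
  lines(x$plate$t, x$plate$Ry, col = 2)
  legend("topright", c("Rx", "Ry"), col = 1:2, lty = 1, bty = "n")
  plot(x$plate$t, x$plate$Ny, type = "l", xlab = "", ylab = "Nx, Ny [N m]")
  lines(x$plate$t, x$plate$Nx, col = 2)
  legend("topright", c("Ny", "Nx"), col = 1:2, lty = 1, bty = "n")
  if (!is.null(x$head)) {
    plot(x$head$t, x$head$Xhdd, type = "l", xlab = "time [s]",
         ylab = "head acc [m/s^2]")
    lines(x$head$t, x$head$Yhdd, col = 2)
  } else {
    plot(x$plate$t, x$plate$Fz, type = "l", xlab = "time [s]",
         ylab = "Fz [N]")
  }
  invisible(x)
}
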