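# COM estimators: per-sample algebraic inversion of the linearized standing
# models, followed by Kalman fusion of displacement and acceleration.
#
# Sign conventions (x forward, y left, z up, right-handed moments) are those
# of the model equations: the sagittal moment balance carries -N_y, the
# frontal one +N_x.  Estimates live in the moving (plate-fixed) frame.

#' Single-pendulum COM estimate (force platform only)
#'
#' Inverts the whole-body inverted-pendulum equations sample by sample.
#' Sagittal plane:
#' `xbdd = (-M Xsdd - Rx)/m_b`;
#' `xb = (C_sag xbdd + M (L_f + l_b) Xsdd + Ny) / (m_b g)`.
#' Frontal plane:
#' `ybdd = (-M Ysdd - Ry)/m_b`;
#' `yb = (J_yb ybdd + M (L_f + l_b) Ysdd - Nx) / (m_b g)` --
#' note the moment sign flip between the planes.
#'
#' @param plane `"sagittal"` or `"frontal"`.
#' @param plate force-plate data frame (`t, Rx, Ry, Fz, Nx, Ny`), with the
#'   horizontal forces already conditioned (high-pass) as desired.
#' @param support support-acceleration data frame (`t, Xsdd, Ysdd`).
#' @param params segment parameters.
#' @param inertias matching composite inertias.
#' @return list with `t`, `xb` (displacement, m), `ab` (acceleration,
#'   m/s^2).
#' @export
estimate_method1 <- function(plane = c("sagittal", "frontal"), plate,
                             support, params, inertias) {
  plane <- match.arg(plane)
  s <- as.list(params$sagittal)
  subj <- params$subject
  M <- subj$M; g <- subj$g
  n <- nrow(plate)
  if (nrow(support) != n)
    stop("plate and support series lengths differ (", n, " vs ",
         nrow(support), ")", call. = FALSE)
  if (s$m_b * g == 0) stop("m_b * g must be nonzero", call. = FALSE)
  lever <- M * (s$L_f + s$l_b)
  if (plane == "sagittal") {
    ab <- (-M * support$Xsdd - plate$Rx) / s$m_b
    xb <- (inertias$C_sag * ab + lever * support$Xsdd + plate$Ny) /
      (s$m_b * g)
  } else {
    ab <- (-M * support$Ysdd - plate$Ry) / s$m_b
    xb <- (inertias$J_yb * ab + lever * support$Ysdd - plate$Nx) /
      (s$m_b * g)
  }
  list(t = plate$t, xb = xb, ab = ab)
}

#' Double-pendulum COM estimate (force platform + head acceleration)
#'
#' Solves, per sample, the 3x3 linear system that couples the two-segment
#' force balance, the moment balance and the head-acceleration kinematics,
#' for the two segment COM accelerations and the whole-body COM
#' displacement; the whole-body COM acceleration is the mass-weighted
#' combination of the segment accelerations.  The coefficient matrix is
#' time-invariant, so one factorization is reused for all samples.
#'
#' @inheritParams estimate_method1
#' @param head data frame `t, Xhdd, Yhdd` -- stationary-frame horizontal
#'   head acceleration.
#' @return list with `t`, `xb` (m), `ab` (m/s^2), and the lower/upper
#'   segment COM accelerations `a1`, `a2` (m/s^2).
#' @export
estimate_method2 <- function(plane = c("sagittal", "frontal"), plate, head,
                             support, params, inertias) {
  plane <- match.arg(plane)
  s <- as.list(params$sagittal); f <- as.list(params$frontal)
  subj <- params$subject
  M <- subj$M; g <- subj$g
  n <- nrow(plate)
  if (nrow(support) != n || nrow(head) != n)
    stop("plate, head and support series must share one grid", call. = FALSE)
  lever <- M * (s$L_f + s$l_b)

  if (plane == "sagittal") {
    A <- rbind(
      c(s$m_1, s$m_2, 0),
      c(inertias$J_x1, inertias$J_x2, -s$m_b * g),
      c((s$l_2 - s$L_2) * s$L_1 / (s$l_1 * s$l_2), s$L_2 / s$l_2, 0))
    rhs <- rbind(-M * support$Xsdd - plate$Rx,
                 -lever * support$Xsdd - plate$Ny,
                 head$Xhdd - support$Xsdd)
    w1 <- s$m_1 / s$m_b; w2 <- s$m_2 / s$m_b
  } else {
    A <- rbind(
      c(2 * f$m_l + f$m_p * f$L_l / f$l_l, f$m_u, 0),
      c(inertias$J_y1, inertias$J_y2, -s$m_b * g),
      c((f$l_u - f$L_u) * f$L_l / (f$l_l * f$l_u), f$L_u / f$l_u, 0))
    rhs <- rbind(-M * support$Ysdd - plate$Ry,
                 -lever * support$Ysdd + plate$Nx,
                 head$Yhdd - support$Ysdd)
    w1 <- (2 * f$m_l * f$l_l + f$m_p * f$L_l) / (s$m_b * f$l_l)
    w2 <- f$m_u / s$m_b
  }
  kap <- kappa(A, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop("segment-coupling matrix is ill-conditioned (condition number ",
         format(kap, digits = 3), "); check the segment parameters",
         call. = FALSE)
  X <- solve(A, rhs)
  list(t = plate$t, xb = X[3, ], ab = w1 * X[1, ] + w2 * X[2, ],
       a1 = X[1, ], a2 = X[2, ])
}

#' Estimate the COM trajectory of a standing trial
#'
#' The front door of the package: conditions the sensor streams, runs one of
#' the four estimation methods, and (for the model-based methods) fuses
#' displacement and acceleration through the Kalman filter to obtain the
#' COM velocity.
#'
#' Methods:
#' \describe{
#'   \item{I}{single-pendulum inversion; force platform only.}
#'   \item{II}{double-pendulum / frontal-linkage inversion; needs the head
#'     acceleration stream (given directly or derived from raw IMU channels
#'     via [imu_horizontal_acceleration()]).  Also yields lower/upper
#'     segment COM accelerations.}
#'   \item{III}{baseline: zero-phase low-pass of the COP.}
#'   \item{IV}{baseline: high-pass-stabilized double integration of the
#'     force-derived COM acceleration.}
#' }
#'
#' @param trial a `com_trial` (simulated or read from files).
#' @param method `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param plane `"sagittal"` (AP) or `"frontal"` (ML).
#' @param highpass_hz zero-phase high-pass corner applied to the horizontal
#'   forces before inversion (default 0.1 Hz; set 0 to disable).
#' @param filter_order Butterworth order of the conditioning filters.
#' @param fuse logical: run the Kalman fusion (methods I/II) to obtain the
#'   velocity (default TRUE).
#' @param kalman optional [kalman_config()]; default configuration if NULL.
#' @param method3_cutoff_hz COP low-pass corner for method III (default 0.5).
#' @param method4_highpass_hz integration-stabilizing high-pass corner for
#'   method IV (default 0.1).
#' @param imu_options list of arguments forwarded to
#'   [imu_horizontal_acceleration()] when the head stream must be derived
#'   from raw IMU channels.
#' @return object of class `"com_estimate"`: list with `t`, `data` (data
#'   frame with columns `xb_raw` [m], `xb` [m], `vb` [m/s], `ab` [m/s^2]
#'   and, for method II, `a1`, `a2` [m/s^2]), `method`, `plane`, `fs`, and
#'   the resolved configuration.
#' @examples
#' tr <- simulate_trial("ankle_AP", seed = 3)
#' est <- estimate_com(tr, method = "II", plane = "sagittal")
#' summary(est)
#' @export
estimate_com <- function(trial, method = c("II", "I", "III", "IV"),
                         plane = c("sagittal", "frontal"),
                         highpass_hz = 0.1, filter_order = 8,
                         fuse = TRUE, kalman = NULL,
                         method3_cutoff_hz = 0.5,
                         method4_highpass_hz = 0.1,
                         imu_options = list()) {
  method <- match.arg(method)
  plane <- match.arg(plane)
  stopifnot(inherits(trial, "com_trial"))
  fs <- trial$fs
  params <- segment_parameters(trial$subject)
  inert <- composite_inertias(params)

  plate <- trial$plate
  if (highpass_hz > 0) {
    plate$Rx <- zero_phase_butterworth(plate$Rx, fs, highpass_hz,
                                       filter_order, "high")
    plate$Ry <- zero_phase_butterworth(plate$Ry, fs, highpass_hz,
                                       filter_order, "high")
  }
  support <- trial$support
  if (is.null(support))
    support <- data.frame(t = plate$t, Xsdd = 0, Ysdd = 0)

  a1 <- a2 <- NULL
  if (method == "I") {
    r <- estimate_method1(plane, plate, support, params, inert)
  } else if (method == "II") {
    head <- trial$head
    if (is.null(head)) {
      if (is.null(trial$imu))
        stop("method II requires a head-acceleration or raw IMU stream",
             call. = FALSE)
      head <- do.call(imu_horizontal_acceleration,
                      c(list(imu = trial$imu, fs = fs), imu_options))
    }
    r <- estimate_method2(plane, plate, head, support, params, inert)
    a1 <- r$a1; a2 <- r$a2
  } else if (method == "III") {
    cop <- compute_cop(trial$plate)   # unfiltered moments for the COP
    r <- estimate_method3(cop, fs, fc = method3_cutoff_hz, plane = plane)
  } else {
    r <- estimate_method4(plane, plate, support, params, fs,
                          highpass_hz = method4_highpass_hz)
  }

  dat <- data.frame(xb_raw = r$xb, xb = r$xb, ab = r$ab)
  vb <- rep(NA_real_, length(r$xb))
  kcfg <- NULL
  if (method %in% c("I", "II") && fuse) {
    kcfg <- if (is.null(kalman)) kalman_config(dt = 1 / fs) else kalman
    fz <- kalman_fuse(r$xb, r$ab, kcfg)
    dat$xb <- fz$displacement
    vb <- fz$velocity
  } else if (method %in% c("III", "IV")) {
    vb <- r$vb
  }
  dat$vb <- vb
  if (!is.null(a1)) { dat$a1 <- a1; dat$a2 <- a2 }

  structure(list(t = r$t, data = dat, method = method, plane = plane,
                 fs = fs, motion = trial$motion, subject = trial$subject,
                 config = list(highpass_hz = highpass_hz,
                               filter_order = filter_order,
                               fuse = fuse, kalman = kcfg,
                               method3_cutoff_hz = method3_cutoff_hz,
                               method4_highpass_hz = method4_highpass_hz)),
            class = "com_estimate")
}

#' @export
print.com_estimate <- function(x, ...) {
  cat(sprintf("COM estimate, method %s, %s plane (%s trial, %g Hz)\n",
              x$method, x$plane,
              if (is.null(x$motion)) "unlabelled" else x$motion, x$fs))
  i <- x$t >= 5 & x$t < min(35, max(x$t))
  if (!any(i)) i <- rep(TRUE, length(x$t))
  cat(sprintf("  displacement RMS %.2f mm", 1000 * sqrt(mean(x$data$xb[i]^2,
                                                             na.rm = TRUE))))
  if (any(is.finite(x$data$vb)))
    cat(sprintf(", velocity RMS %.2f mm/s",
                1000 * sqrt(mean(x$data$vb[i]^2, na.rm = TRUE))))
  cat("\n")
  invisible(x)
}

#' @export
summary.com_estimate <- function(object, ...) {
  i <- object$t >= 5 & object$t < min(35, max(object$t))
  d <- object$data[i, , drop = FALSE]
  out <- data.frame(
    quantity = names(d),
    rms = sapply(d, function(v) sqrt(mean(v^2, na.rm = TRUE))),
    min = sapply(d, min, na.rm = TRUE),
    max = sapply(d, max, na.rm = TRUE))
  rownames(out) <- NULL
  cat(sprintf("COM estimate, method %s, %s plane; evaluation window %s\n",
              object$method, object$plane, "[5 s, 35 s)"))
  print(out, digits = 4)
  invisible(out)
}

#' @export
plot.com_estimate <- function(x, truth = NULL, ...) {
  op <- par(mfrow = c(2, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(par(op))
  plot(x$t, 1000 * x$data$xb, type = "l", col = 4, xlab = "",
       ylab = "COM displacement [mm]",
       main = sprintf("method %s, %s", x$method, x$plane))
  if (!is.null(truth)) {
    td <- if (inherits(truth, "com_truth")) truth[[x$plane]] else truth
    lines(td$t, 1000 * td$xb, col = 1)
    legend("topright", c("truth", "estimate"), col = c(1, 4), lty = 1,
           bty = "n")
  }
  if (any(is.finite(x$data$vb))) {
    plot(x$t, 1000 * x$data$vb, type = "l", col = 4, xlab = "time [s]",
         ylab = "COM velocity [mm/s]")
    if (!is.null(truth)) {
      td <- if (inherits(truth, "com_truth")) truth[[x$plane]] else truth
      if (!is.null(td$xbd)) lines(td$t, 1000 * td$xbd, col = 1)
    }
  } else {
    plot(x$t, 1000 * x$data$ab, type = "l", col = 4, xlab = "time [s]",
         ylab = "COM acceleration [mm/s^2]")
  }
  invisible(x)
}
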