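# Exact nonlinear Newton-Euler oracle.
#
# The estimators invert small-angle equations; to measure what that
# linearization costs, this module evaluates the exact planar rigid-body
# dynamics of the same linkages -- no small-angle step anywhere -- and
# synthesizes the plate reaction, ideal head-IMU channels and exact head
# acceleration from prescribed joint trajectories.  It is hand-derived from
# the moment-of-momentum balance about the (possibly accelerating) plate
# origin, a different route from the linear forms, and is validated in the
# test suite by momentum/energy audits rather than by comparison with the
# code it is meant to check.
#
# Conventions: x forward, y left, z up.  The plate measures the action of
# the body on it: R = -F_reaction (horizontal), Fz = +F_reaction,z, and the
# moments satisfy N_y = -(reaction moment about y), N_x = +(y-displacement
# moment balance), matching the signs of the linearized forms (a static
# forward lean x_b gives N_y = m_b g x_b > 0; a static left lean y_b gives
# N_x = -m_b g y_b).  The foot (mass M - m_b) rests on the plate with its
# COM at the plate origin.

# acceleration of a point at radius r on a segment with angle series th:
# relative to the (translating) support, split into horizontal / vertical
pt_acc <- function(r, th, thd, thdd) {
  list(h = r * (thdd * cos(th) - thd^2 * sin(th)),
       v = r * (-thdd * sin(th) - thd^2 * cos(th)))
}

# Moment-of-momentum balance about the moving plate origin for a set of
# point-mass/inertia segments:  sum_i [J_i thdd_i + m_i (z_i a_h,abs -
# x_i a_v)] - g sum_i m_i x_i  =  reaction moment about +y (sagittal form).
# Inputs are lists of per-segment series.
plate_moment <- function(J, thdd, m, xrel, z, ah_abs, av, g) {
  Mm <- 0
  for (i in seq_along(m))
    Mm <- Mm + (if (!is.null(J[[i]])) J[[i]] * thdd[[i]] else 0) +
      m[[i]] * (z[[i]] * ah_abs[[i]] - xrel[[i]] * av[[i]])
  grav <- 0
  for (i in seq_along(m)) grav <- grav + m[[i]] * xrel[[i]]
  Mm - g * grav
}

#' Exact nonlinear inverse dynamics (Newton-Euler oracle)
#'
#' Computes the exact planar reaction force and moment at the plate, ideal
#' head-IMU channels (specific force including gravity, angular rate) and
#' the exact stationary-frame head acceleration for the rigid double
#' pendulum (sagittal) or the parallel-leg/translating-pelvis linkage
#' (frontal), without any small-angle approximation.
#'
#' @param truth a `com_truth` from [make_trajectories()] (angles only is
#'   enough; any linearized kinematics columns are ignored).
#' @param params segment parameters.
#' @param plane `"sagittal"` or `"frontal"`.
#' @return list with `plate`, `head` (exact `Xhdd`/`Yhdd`), `imu`
#'   (`t, ax, ay, az, gx, gy, gz`), `support`, and `truth` -- the input
#'   truth with *exact* nonlinear COM kinematics for the simulated plane
#'   (the other plane's series are zero).
#' @export
inverse_dynamics_nonlinear <- function(truth, params,
                                       plane = c("sagittal", "frontal")) {
  plane <- match.arg(plane)
  stopifnot(inherits(truth, "com_truth"))
  s <- as.list(params$sagittal); f <- as.list(params$frontal)
  subj <- params$subject
  M <- subj$M; g <- subj$g
  m_f <- M - s$m_b                      # foot mass, static on the plate
  sup <- truth$support
  tt <- sup$t
  n <- length(tt)
  zero <- numeric(n)

  if (plane == "sagittal") {
    d <- truth$sagittal
    th1 <- d$th1; th1d <- d$th1d; th1dd <- d$th1dd
    th2 <- d$th2; th2d <- d$th2d; th2dd <- d$th2dd
    Xsdd <- sup$Xsdd
    # segment COM positions relative to the plate origin, exact
    x1 <- s$l_1 * sin(th1);  z1 <- s$L_f + s$l_1 * cos(th1)
    x2 <- s$L_1 * sin(th1) + s$l_2 * sin(th2)
    z2 <- s$L_f + s$L_1 * cos(th1) + s$l_2 * cos(th2)
    a1 <- pt_acc(s$l_1, th1, th1d, th1dd)
    a2a <- pt_acc(s$L_1, th1, th1d, th1dd)
    a2b <- pt_acc(s$l_2, th2, th2d, th2dd)
    a1h <- a1$h; a1v <- a1$v
    a2h <- a2a$h + a2b$h; a2v <- a2a$v + a2b$v
    Fx <- s$m_1 * (a1h + Xsdd) + s$m_2 * (a2h + Xsdd) + m_f * Xsdd
    Fzr <- s$m_1 * (a1v + g) + s$m_2 * (a2v + g) + m_f * g
    Mreact <- plate_moment(
      J = list(s$J_1, s$J_2), thdd = list(th1dd, th2dd),
      m = list(s$m_1, s$m_2), xrel = list(x1, x2), z = list(z1, z2),
      ah_abs = list(a1h + Xsdd, a2h + Xsdd), av = list(a1v, a2v), g = g)
    plate <- data.frame(t = tt, Rx = -Fx, Ry = zero, Fz = Fzr,
                        Nx = zero, Ny = -Mreact)
    # head point and IMU (pitch = upper-body angle th2)
    ha <- pt_acc(s$L_1, th1, th1d, th1dd)
    hb <- pt_acc(s$L_2, th2, th2d, th2dd)
    hh <- ha$h + hb$h + Xsdd            # absolute horizontal
    hv <- ha$v + hb$v                   # vertical
    imu <- data.frame(
      t = tt,
      ax = cos(th2) * hh - sin(th2) * (hv + g),
      ay = zero,
      az = sin(th2) * hh + cos(th2) * (hv + g),
      gx = zero, gy = th2d, gz = zero)
    head <- data.frame(t = tt, Xhdd = hh, Yhdd = zero)
    # exact COM kinematics for ground truth
    xb <- (s$m_1 * x1 + s$m_2 * x2) / s$m_b
    xbd <- (s$m_1 * s$l_1 * cos(th1) * th1d +
              s$m_2 * (s$L_1 * cos(th1) * th1d + s$l_2 * cos(th2) * th2d)) /
      s$m_b
    xbdd <- (s$m_1 * a1h + s$m_2 * a2h) / s$m_b
    d$x1 <- x1; d$x2 <- x2; d$x1dd <- a1h; d$x2dd <- a2h
    d$xb <- xb; d$xbd <- xbd; d$xbdd <- xbdd
    d$xh <- s$L_1 * sin(th1) + s$L_2 * sin(th2); d$xhdd <- hh - Xsdd
    truth$sagittal <- d
    truth$frontal[c("x1", "x2", "x1dd", "x2dd", "xb", "xbd", "xbdd",
                    "xh", "xhdd")] <- 0
  } else {
    d <- truth$frontal
    thl <- d$th1; thld <- d$th1d; thldd <- d$th1dd
    thu <- d$th2; thud <- d$th2d; thudd <- d$th2dd
    Ysdd <- sup$Ysdd
    # both legs rotate together; the pelvis translates with the hip point
    # (no rotation), the upper body rotates about the waist
    yl <- f$l_l * sin(thl);  zl <- f$L_f + f$l_l * cos(thl)
    yp <- f$L_l * sin(thl);  zp <- f$L_f + f$L_l * cos(thl) + f$l_p
    yu <- f$L_l * sin(thl) + f$l_u * sin(thu)
    zu <- f$L_f + f$L_l * cos(thl) + f$L_p + f$l_u * cos(thu)
    al <- pt_acc(f$l_l, thl, thld, thldd)
    ap <- pt_acc(f$L_l, thl, thld, thldd)       # pelvis: pure translation
    aua <- pt_acc(f$L_l, thl, thld, thldd)
    aub <- pt_acc(f$l_u, thu, thud, thudd)
    auh <- aua$h + aub$h; auv <- aua$v + aub$v
    Fy <- 2 * f$m_l * (al$h + Ysdd) + f$m_p * (ap$h + Ysdd) +
      f$m_u * (auh + Ysdd) + m_f * Ysdd
    Fzr <- 2 * f$m_l * (al$v + g) + f$m_p * (ap$v + g) +
      f$m_u * (auv + g) + m_f * g
    Lam <- plate_moment(
      J = list(2 * f$J_l, NULL, f$J_u),
      thdd = list(thldd, NULL, thudd),
      m = list(2 * f$m_l, f$m_p, f$m_u),
      xrel = list(yl, yp, yu), z = list(zl, zp, zu),
      ah_abs = list(al$h + Ysdd, ap$h + Ysdd, auh + Ysdd),
      av = list(al$v, ap$v, auv), g = g)
    plate <- data.frame(t = tt, Rx = zero, Ry = -Fy, Fz = Fzr,
                        Nx = Lam, Ny = zero)
    ha <- pt_acc(f$L_l, thl, thld, thldd)
    hb <- pt_acc(f$L_u, thu, thud, thudd)
    hh <- ha$h + hb$h + Ysdd
    hv <- ha$v + hb$v
    imu <- data.frame(
      t = tt,
      ax = zero,
      ay = cos(thu) * hh - sin(thu) * (hv + g),
      az = sin(thu) * hh + cos(thu) * (hv + g),
      gx = -thud, gy = zero, gz = zero)
    head <- data.frame(t = tt, Xhdd = zero, Yhdd = hh)
    yb <- (2 * f$m_l * yl + f$m_p * yp + f$m_u * yu) / s$m_b
    ybd <- (2 * f$m_l * f$l_l * cos(thl) * thld +
              f$m_p * f$L_l * cos(thl) * thld +
              f$m_u * (f$L_l * cos(thl) * thld +
                         f$l_u * cos(thu) * thud)) / s$m_b
    ybdd <- (2 * f$m_l * al$h + f$m_p * ap$h + f$m_u * auh) / s$m_b
    d$x1 <- yl; d$x2 <- yu; d$x1dd <- al$h; d$x2dd <- auh
    d$xb <- yb; d$xbd <- ybd; d$xbdd <- ybdd
    d$xh <- f$L_l * sin(thl) + f$L_u * sin(thu); d$xhdd <- hh - Ysdd
    truth$frontal <- d
    truth$sagittal[c("x1", "x2", "x1dd", "x2dd", "xb", "xbd", "xbdd",
                     "xh", "xhdd")] <- 0
  }
  truth$model <- "nonlinear"
  list(plate = plate, head = head, imu = imu,
       support = data.frame(t = tt, Xsdd = sup$Xsdd, Ysdd = sup$Ysdd),
       truth = truth)
}
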