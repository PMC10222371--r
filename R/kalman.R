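# Constant-velocity Kalman filter fusing a displacement observation with an
# acceleration input.  This is the smoother applied to the pendulum-model
# estimates: the moment-equation displacement is the observation y, the
# force-equation acceleration is the control input u, and the state is
# (displacement, velocity).

#' State-space matrices of the fusion filter
#'
#' Discrete constant-velocity kinematics driven by sampled acceleration:
#' `x(k) = A x(k-1) + b u(k)`, `y(k) = c x(k)` with
#' `A = [[1, dt], [0, 1]]`, `b = (dt^2/2, dt)`, `c = (1, 0)`.
#'
#' @param dt sampling interval, s.
#' @return list with `A` (2x2), `b` (length 2), `c` (length 2).
#' @export
build_kalman_matrices <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive scalar", call. = FALSE)
  list(A = matrix(c(1, 0, dt, 1), 2, 2),
       b = c(dt^2 / 2, dt),
       c = c(1, 0))
}

#' Configuration of the displacement/velocity fusion filter
#'
#' Defaults follow the design used throughout this package:
#' `Q_w = diag(0.0025, 0.04)` and `Q_v = 1`, with the filter operating on
#' signals expressed in millimetres (so `Q_v = 1 mm^2` is a plausible
#' observation-noise scale for a force-platform-derived displacement).  The
#' filter's dynamics depend only on the ratio `Q_w / Q_v`, so the working
#' unit affects bookkeeping, not behaviour; conversion to and from the
#' working unit is centralized in [kalman_fuse()].
#'
#' @param dt sampling interval, s.
#' @param Q_w 2x2 process-noise covariance (working-unit^2, per step).
#' @param Q_v scalar observation-noise variance (working-unit^2).
#' @param unit working length unit, `"mm"` or `"m"`; inputs in metres are
#'   scaled into this unit inside the filter.
#' @param x0 initial state; default `(first displacement sample, 0)`.
#' @param P0 initial covariance; default `diag(Q_v, 100 * Q_w[1,1])`.
#' @return list of class `"kalman_config"`.
#' @export
kalman_config <- function(dt, Q_w = diag(c(0.0025, 0.04)), Q_v = 1,
                          unit = c("mm", "m"), x0 = NULL, P0 = NULL) {
  unit <- match.arg(unit)
  Q_w <- as.matrix(Q_w)
  if (!all(dim(Q_w) == c(2, 2)) || max(abs(Q_w - t(Q_w))) > 1e-12)
    stop("'Q_w' must be a symmetric 2x2 matrix", call. = FALSE)
  if (any(eigen(Q_w, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("'Q_w' must be positive semidefinite", call. = FALSE)
  if (!is.numeric(Q_v) || Q_v <= 0) stop("'Q_v' must be > 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (is.null(P0)) P0 <- diag(c(Q_v, 100 * Q_w[1, 1]))
  structure(list(dt = dt, Q_w = Q_w, Q_v = Q_v, unit = unit,
                 x0 = x0, P0 = P0),
            class = "kalman_config")
}

#' Fuse displacement and acceleration into displacement + velocity
#'
#' Strictly causal Kalman recursion: predict with the constant-velocity
#' model driven by the acceleration input, update with the displacement
#' observation.  With a consistent (displacement, acceleration) pair the
#' output tracks with essentially no phase delay, which is what makes the
#' fused estimate usable online.
#'
#' Non-finite samples are treated as gaps: the filter coasts on prediction
#' (without the affected input), the corresponding outputs are set to `NA`,
#' and the gap indices are attached as attribute `"gaps"` with a warning --
#' gaps never pass through silently.
#'
#' @param displacement observed displacement series (m).
#' @param acceleration acceleration input series (m/s^2), same length.
#' @param cfg a [kalman_config()].
#' @param diagnostics logical; if TRUE the per-step posterior covariance is
#'   returned as an n x 3 matrix `P_history` (p11, p12, p22) together with
#'   the per-step gain `G_history` (n x 2).
#' @return list with `displacement` (m), `velocity` (m/s), the final
#'   covariance `P` and gain `G` (working units), plus histories if
#'   requested.
#' @export
kalman_fuse <- function(displacement, acceleration, cfg,
                        diagnostics = FALSE) {
  if (!inherits(cfg, "kalman_config"))
    stop("'cfg' must be a kalman_config object", call. = FALSE)
  n <- length(displacement)
  if (length(acceleration) != n)
    stop("displacement and acceleration must have equal length",
         call. = FALSE)
  scale <- if (cfg$unit == "mm") 1000 else 1
  y <- displacement * scale
  u <- acceleration * scale
  mats <- build_kalman_matrices(cfg$dt)
  A <- mats$A; b <- mats$b; cvec <- mats$c
  P <- cfg$P0
  x <- cfg$x0
  if (is.null(x)) {
    y1 <- y[is.finite(y)][1]
    x <- c(if (is.na(y1)) 0 else y1, 0)
  }
  gaps <- which(!is.finite(y) | !is.finite(u))
  xs <- matrix(NA_real_, n, 2)
  G <- c(0, 0)
  Ph <- if (diagnostics) matrix(NA_real_, n, 3) else NULL
  Gh <- if (diagnostics) matrix(NA_real_, n, 2) else NULL
  for (k in seq_len(n)) {
    ok_u <- is.finite(u[k]); ok_y <- is.finite(y[k])
    xm <- A %*% x + if (ok_u) b * u[k] else 0
    Pm <- A %*% P %*% t(A) + cfg$Q_w
    if (ok_y) {
      S <- as.numeric(t(cvec) %*% Pm %*% cvec + cfg$Q_v)
      G <- as.numeric(Pm %*% cvec) / S
      x <- as.numeric(xm) + G * (y[k] - as.numeric(t(cvec) %*% xm))
      P <- (diag(2) - G %*% t(cvec)) %*% Pm
      P <- (P + t(P)) / 2                     # enforce symmetry
    } else {
      x <- as.numeric(xm)
      P <- Pm
    }
    if (ok_u && ok_y) xs[k, ] <- x
    if (diagnostics) {
      Ph[k, ] <- c(P[1, 1], P[1, 2], P[2, 2])
      Gh[k, ] <- G
    }
  }
  if (length(gaps)) {
    warning(length(gaps), " non-finite input sample(s) propagated as gaps",
            call. = FALSE)
  }
  out <- list(displacement = xs[, 1] / scale,
              velocity = xs[, 2] / scale,
              P = P, G = G)
  if (diagnostics) {
    out$P_history <- Ph
    out$G_history <- Gh
  }
  attr(out, "gaps") <- gaps
  out
}
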