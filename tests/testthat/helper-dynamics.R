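# Independent dynamics machinery for auditing the Newton-Euler oracle:
# a Lagrangian free (unactuated) double pendulum on a fixed base, integrated
# with deSolve, plus numerical-differentiation audits of momentum balances.

# mass matrix / bias / gravity terms for absolute angles (th1, th2):
# M(th) thdd + C(th, thd) + G(th) = 0  (torque-free)
free_dp_derivs <- function(t, y, p) {
  th1 <- y[1]; th2 <- y[2]; w1 <- y[3]; w2 <- y[4]
  M11 <- p$m1 * p$l1^2 + p$J1 + p$m2 * p$L1^2
  M22 <- p$m2 * p$l2^2 + p$J2
  M12 <- p$m2 * p$L1 * p$l2 * cos(th1 - th2)
  s <- sin(th1 - th2)
  c1 <- p$m2 * p$L1 * p$l2 * s * w2^2 - p$g * (p$m1 * p$l1 + p$m2 * p$L1) *
    sin(th1)
  c2 <- -p$m2 * p$L1 * p$l2 * s * w1^2 - p$g * p$m2 * p$l2 * sin(th2)
  acc <- solve(matrix(c(M11, M12, M12, M22), 2, 2), -c(c1, c2))
  list(c(w1, w2, acc[1], acc[2]))
}

free_dp_params <- function(params) {
  s <- as.list(params$sagittal)
  list(m1 = s$m_1, m2 = s$m_2, J1 = s$J_1, J2 = s$J_2,
       l1 = s$l_1, l2 = s$l_2, L1 = s$L_1,
       g = params$subject$g)
}

# kinetic and potential energy of the double pendulum (ankle at origin)
free_dp_energy <- function(y, p) {
  th1 <- y[, 1]; th2 <- y[, 2]; w1 <- y[, 3]; w2 <- y[, 4]
  v2sq <- p$L1^2 * w1^2 + p$l2^2 * w2^2 +
    2 * p$L1 * p$l2 * cos(th1 - th2) * w1 * w2
  KE <- 0.5 * (p$m1 * p$l1^2 + p$J1) * w1^2 + 0.5 * p$J2 * w2^2 +
    0.5 * p$m2 * v2sq
  PE <- p$g * (p$m1 * p$l1 * cos(th1) +
                 p$m2 * (p$L1 * cos(th1) + p$l2 * cos(th2)))
  list(KE = KE, PE = PE)
}

# central-difference derivative used by the audits (independent of the
# package's differentiate(), which is itself under test elsewhere)
numdiff <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}
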