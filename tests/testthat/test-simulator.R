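test_that("sway waveform has exactly the 20-harmonic spectrum and the target RMS", {
  sw <- sway_waveform(40, 100, rms_amplitude = 0.01, seed = 3)
  expect_equal(sqrt(mean(sw$x^2)), 0.01, tolerance = 0.02)
  # 40 s record: frequency bins at k/40 Hz; harmonics at 0.05k -> bins 2k
  n <- 4000
  X <- Mod(fft(sw$x[1:n]))[1:(n / 2)]
  fbin <- (seq_len(n / 2) - 1) / 40
  big <- which(X > max(X) * 1e-6)
  expect_equal(sort(fbin[big]), seq(0.05, 1, by = 0.05), tolerance = 1e-12)
  expect_equal(length(big), 20L)
  # determinism and phase randomization
  expect_identical(sway_waveform(40, 100, 0.01, seed = 3)$x, sw$x)
  sw2 <- sway_waveform(40, 100, 0.01, seed = 4)
  expect_false(isTRUE(all.equal(sw2$x, sw$x)))
  X2 <- Mod(fft(sw2$x[1:n]))[1:(n / 2)]
  expect_equal(X2[big], X[big], tolerance = 1e-6)  # same magnitudes
  expect_equal(sway_waveform(10, 100, 0, seed = 1)$x, numeric(1001))
})

test_that("ankle trajectories peak at the commanded frequency", {
  tr <- make_trajectories(motion_spec("ankle_AP", seed = 2))
  th <- tr$sagittal$th1
  n <- 4000
  X <- Mod(fft(th[1:n]))[2:(n / 2)]
  fpk <- (which.max(X)) / 40
  expect_equal(fpk, 0.25)
  # ankle strategy: the two segments move together
  expect_gt(cor(tr$sagittal$th1, tr$sagittal$th2), 0.95)
})

test_that("hip trajectories are counter-phase with small COM excursion", {
  vol <- make_trajectories(motion_spec("hip_AP", seed = 2,
                                       background = FALSE))
  expect_lt(cor(vol$sagittal$th1, vol$sagittal$th2), -0.9)
  tr <- make_trajectories(motion_spec("hip_AP", seed = 2))
  tk <- truth_kinematics(tr, ref_params)
  i <- tk$sagittal$t >= 5 & tk$sagittal$t < 35
  expect_lt(sd(tk$sagittal$xb[i]), 0.010)            # COM stays < 10 mm
  expect_gt(sqrt(mean(tk$sagittal$x1dd[i]^2)), 0.1)  # accelerations large
})

test_that("quiet standing is reproducible with the commanded sway RMS", {
  tr1 <- make_trajectories(motion_spec("quiet", seed = 9))
  tr2 <- make_trajectories(motion_spec("quiet", seed = 9))
  expect_identical(tr1$sagittal, tr2$sagittal)
  i <- tr1$sagittal$t >= 5 & tr1$sagittal$t < 35
  expect_equal(sd(tr1$sagittal$th1[i]), 0.003, tolerance = 0.2)
})

test_that("ground truth is kinematically self-consistent", {
  tk <- truth_kinematics(make_trajectories(motion_spec("ankle_AP", seed = 4)),
                         ref_params)
  d <- tk$sagittal
  dt <- 1 / tk$fs
  xbdd_num <- numdiff(numdiff(d$xb, dt), dt)
  i <- 3:(nrow(d) - 2)
  # twice-applied central differences carry a (2 pi f dt)^2-scale error of
  # their own (~0.2% for the 2 Hz content at 100 Hz)
  expect_lt(max(abs(xbdd_num[i] - d$xbdd[i])), 5e-3 * max(abs(d$xbdd)))
})

test_that("linear and nonlinear generators agree quadratically at small angles", {
  # channel-wise discrepancy scales ~ amplitude^2: halving the amplitude
  # cuts it by four
  disc <- sapply(c(2, 1, 0.5) * pi / 180, function(a) {
    spec <- motion_spec("ankle_AP", amplitude = a, seed = 5,
                        background = FALSE)
    truth <- make_trajectories(spec)
    lin <- inverse_dynamics_linear(truth_kinematics(truth, ref_params),
                                   ref_params, ref_inertias)
    nl <- inverse_dynamics_nonlinear(truth, ref_params, plane = "sagittal")
    c(Ny = sqrt(mean((lin$plate$Ny - nl$plate$Ny)^2)),
      Rx = sqrt(mean((lin$plate$Rx - nl$plate$Rx)^2)),
      head = sqrt(mean((lin$head$Xhdd - nl$head$Xhdd)^2)))
  })
  for (ch in rownames(disc)) {
    expect_lt(disc[ch, 2], disc[ch, 1] / 3)       # 1 deg vs 2 deg
    expect_lt(disc[ch, 3], disc[ch, 1] / 4)       # 0.5 deg vs 2 deg
  }
})

test_that("oracle reaction channels satisfy the momentum balances", {
  # independent audit: differentiate exact positions numerically and check
  # the force/moment outputs against d(momentum)/dt
  # a fine grid keeps the audit's own differentiation error well below the
  # tolerance, so any structural error in the oracle stands out
  spec <- motion_spec("hip_AP", amplitude = 0.03, seed = 8, duration = 10,
                      fs = 500, background = FALSE)
  truth <- make_trajectories(spec)
  nl <- inverse_dynamics_nonlinear(truth, ref_params, plane = "sagittal")
  s <- as.list(ref_params$sagittal)
  g <- ref_subject$g
  d <- truth$sagittal
  dt <- 1 / truth$fs
  x1 <- s$l_1 * sin(d$th1); z1 <- s$L_f + s$l_1 * cos(d$th1)
  x2 <- s$L_1 * sin(d$th1) + s$l_2 * sin(d$th2)
  z2 <- s$L_f + s$L_1 * cos(d$th1) + s$l_2 * cos(d$th2)
  # linear momentum: Rx = -d/dt(sum m xdot)
  px <- s$m_1 * numdiff(x1, dt) + s$m_2 * numdiff(x2, dt)
  Rx_audit <- -numdiff(px, dt)
  i <- 5:(length(px) - 4)
  expect_lt(max(abs(Rx_audit[i] - nl$plate$Rx[i]), na.rm = TRUE),
            1e-3 * max(abs(nl$plate$Rx)))
  # vertical: Fz = total weight + d/dt(sum m zdot)
  pz <- s$m_1 * numdiff(z1, dt) + s$m_2 * numdiff(z2, dt)
  Fz_audit <- ref_subject$M * g + numdiff(pz, dt)
  expect_lt(max(abs(Fz_audit[i] - nl$plate$Fz[i]), na.rm = TRUE),
            1e-3 * max(abs(nl$plate$Fz - ref_subject$M * g)))
  # angular momentum about the plate origin:
  # N_y = g sum(m x) - d/dt [ sum(J thd + m (z xdot - x zdot)) ]
  H <- s$J_1 * numdiff(d$th1, dt) + s$J_2 * numdiff(d$th2, dt) +
    s$m_1 * (z1 * numdiff(x1, dt) - x1 * numdiff(z1, dt)) +
    s$m_2 * (z2 * numdiff(x2, dt) - x2 * numdiff(z2, dt))
  Ny_audit <- g * (s$m_1 * x1 + s$m_2 * x2) - numdiff(H, dt)
  expect_lt(max(abs(Ny_audit[i] - nl$plate$Ny[i]), na.rm = TRUE),
            1e-3 * max(abs(nl$plate$Ny)))
})

test_that("free double pendulum conserves energy (work-energy audit)", {
  skip_if_not_installed("deSolve")
  p <- free_dp_params(ref_params)
  tt <- seq(0, 1.2, by = 1e-3)
  y0 <- c(0.25, -0.15, 0, 0)
  sol <- deSolve::ode(y0, tt, free_dp_derivs, p, method = "ode45")
  en <- free_dp_energy(sol[, 2:5], p)
  # fixed base and torque-free joints: plate power is identically zero and
  # dKE/dt must equal the gravity power, i.e. KE + PE constant
  E <- en$KE + en$PE
  dKE <- numdiff(en$KE, 1e-3)
  Pgrav <- -numdiff(en$PE, 1e-3)
  i <- 200:1000
  expect_lt(max(abs(dKE[i] - Pgrav[i])), 1e-3 * max(abs(dKE[i])))
  expect_lt(diff(range(E)), 1e-6 * max(en$KE))
})

test_that("noise injection is seeded, reproducible and optional", {
  tr <- simulate_trial("quiet", seed = 3)
  clean <- add_noise(tr, noise_spec(force_sd = 0, moment_sd = 0, fz_sd = 0,
                                    head_acc_sd = 0, imu_acc_sd = 0,
                                    imu_gyro_sd = 0, support_sd = 0))
  expect_identical(clean$plate, tr$plate)
  expect_identical(clean$head, tr$head)
  n1 <- add_noise(tr, noise_spec(seed = 7))
  n2 <- add_noise(tr, noise_spec(seed = 7))
  expect_identical(n1$plate, n2$plate)
  n3 <- add_noise(tr, noise_spec(seed = 8))
  expect_false(isTRUE(all.equal(n3$plate$Rx, n1$plate$Rx)))
})

test_that("a 20 ms head-stream offset degrades the two-segment estimate", {
  rmse_at <- function(off) {
    tr <- simulate_trial("hip_AP", seed = 11,
                         noise = noise_spec(seed = 12,
                                            head_sync_offset = off))
    e <- estimate_com(tr, "II", "sagittal")
    rmse_windowed(e$data$xb, tr$truth$sagittal$xb, tr$fs)
  }
  expect_gt(rmse_at(0.020), rmse_at(0))
})
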