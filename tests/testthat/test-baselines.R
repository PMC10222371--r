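fs <- 100

test_that("COP follows the plate moments with the static-consistency signs", {
  n <- 1001
  t <- (seq_len(n) - 1) / fs
  M <- ref_subject$M
  plate <- data.frame(t = t, Rx = 0, Ry = 0, Fz = M * 9.81, Nx = 0, Ny = 0)
  cop <- compute_cop(plate)
  expect_equal(cop$COPx, rep(0, n))
  expect_equal(cop$COPy, rep(0, n))
  plate$Ny <- M * 9.81 * 0.010
  cop <- compute_cop(plate)
  expect_equal(cop$COPx, rep(0.010, n), tolerance = 1e-12)
  # scale invariance in the plate channels
  plate2 <- plate
  plate2[c("Rx", "Ry", "Fz", "Nx", "Ny")] <-
    2.7 * plate2[c("Rx", "Ry", "Fz", "Nx", "Ny")]
  expect_equal(compute_cop(plate2), cop, tolerance = 1e-12)
  plate$Fz[5] <- -1
  expect_error(compute_cop(plate), "positive")
})

test_that("a static lean puts the COP at the body-mass-weighted COM projection", {
  # static equilibrium: COP = (m_b/M) x_b
  n <- 1001
  t <- (seq_len(n) - 1) / fs
  s <- ref_params$sagittal
  xb <- 0.015
  plate <- data.frame(t = t, Rx = 0, Ry = 0, Fz = ref_subject$M * 9.81,
                      Nx = 0, Ny = s[["m_b"]] * 9.81 * xb)
  cop <- compute_cop(plate)
  expect_equal(cop$COPx / ((s[["m_b"]] / ref_subject$M) * xb),
               rep(1, n), tolerance = 1e-3)
})

test_that("COP filtering passes DC and rejects fast oscillations", {
  t <- (0:4000) / fs
  cop <- data.frame(t = t, COPx = 0.02, COPy = 0)
  m3 <- estimate_method3(cop, fs, fc = 0.5)
  expect_equal(m3$xb, rep(0.02, length(t)), tolerance = 1e-6)
  cop5 <- data.frame(t = t, COPx = 0.01 * sin(2 * pi * 5 * t), COPy = 0)
  m3 <- estimate_method3(cop5, fs, fc = 0.5)
  i <- t >= 5 & t < 35
  expect_lt(sqrt(mean(m3$xb[i]^2)), 0.01 * sqrt(mean(cop5$COPx[i]^2)))
  expect_error(estimate_method3(cop, fs, fc = 60), "fs/2")
})

test_that("COP filtering tracks the COM in quiet standing", {
  tr <- simulate_trial("quiet", seed = 21, noise = noise_spec(seed = 22))
  e3 <- estimate_com(tr, "III", "sagittal")
  cc <- pearson_cc(e3$data$xb, tr$truth$sagittal$xb, fs)
  expect_gt(cc, 0.95)
})

test_that("double integration recovers in-band motion and rejects drift", {
  z <- data.frame(t = (0:4000) / fs, Rx = 0, Ry = 0,
                  Fz = ref_subject$M * 9.81, Nx = 0, Ny = 0)
  sup <- data.frame(t = z$t, Xsdd = 0, Ysdd = 0)
  m4 <- estimate_method4("sagittal", z, sup, ref_params, fs)
  expect_equal(m4$xb, rep(0, nrow(z)), tolerance = 1e-12)

  # band-limited voluntary motion, noise-free: high correlation
  tr <- simulate_trial(motion_spec("ankle_AP", seed = 23,
                                   background = FALSE))
  e4 <- estimate_com(tr, "IV", "sagittal")
  expect_gt(pearson_cc(e4$data$xb, tr$truth$sagittal$xb, fs), 0.98)

  # a force drift ramp must not grow secularly after double integration
  trd <- simulate_trial("ankle_AP", seed = 24,
                        noise = noise_spec(seed = 25,
                                           force_drift_rate = 0.01))
  e4d <- estimate_com(trd, "IV", "sagittal")
  expect_lt(max(abs(e4d$data$xb)), 0.1)
  # no growth: the last third is no larger than the middle third
  n <- length(e4d$data$xb)
  expect_lt(sqrt(mean(e4d$data$xb[(2 * n / 3):n]^2)),
            3 * sqrt(mean(e4d$data$xb[(n / 3):(2 * n / 3)]^2)))
})

test_that("the two-segment method beats double integration in quiet standing", {
  tr <- simulate_trial("quiet", seed = 26, noise = noise_spec(seed = 27))
  e2 <- estimate_com(tr, "II", "sagittal")
  e4 <- estimate_com(tr, "IV", "sagittal")
  td <- tr$truth$sagittal
  expect_gt(rmse_windowed(e4$data$xb, td$xb, fs),
            rmse_windowed(e2$data$xb, td$xb, fs))
})
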