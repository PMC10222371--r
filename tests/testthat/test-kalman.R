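fs <- 100
dt <- 1 / fs

test_that("state-space matrices have the prescribed structure", {
  m <- build_kalman_matrices(0.01)
  expect_equal(m$A, matrix(c(1, 0, 0.01, 1), 2, 2))
  expect_equal(m$b, c(5e-5, 0.01))
  expect_equal(m$c, c(1, 0))
  expect_equal(build_kalman_matrices(1)$b, c(0.5, 1))
  for (d in c(0.001, 0.02, 1, 7)) {
    A <- build_kalman_matrices(d)$A
    expect_equal(diag(A), c(1, 1))
    expect_equal(A[2, 1], 0)
    expect_equal(A[1, 2], d)
  }
  expect_error(build_kalman_matrices(0), "positive")
})

test_that("zero input yields identically zero output", {
  n <- 500
  f <- kalman_fuse(numeric(n), numeric(n), kalman_config(dt))
  expect_equal(f$displacement, numeric(n))
  expect_equal(f$velocity, numeric(n))
})

test_that("covariance stays symmetric PSD and the gain bounded over 1e5 random steps", {
  set.seed(99)
  n <- 1e5
  f <- kalman_fuse(rnorm(n), rnorm(n), kalman_config(dt),
                   diagnostics = TRUE)
  P <- f$P_history
  expect_true(all(P[, 1] >= 0))
  expect_true(all(P[, 3] >= 0))
  # PSD: determinant of the symmetric 2x2 non-negative
  expect_true(all(P[, 1] * P[, 3] - P[, 2]^2 >= -1e-12))
  # steady-state position gain in (0, 1)
  G1 <- f$G_history[, 1]
  expect_true(all(G1[-1] > 0 & G1[-1] < 1))
})

test_that("constant-acceleration truth is tracked within 0.1% after 2 s", {
  tt <- seq(0, 10, by = dt)
  a <- 0.5
  x <- 0.5 * a * tt^2
  v <- a * tt
  f <- kalman_fuse(x, rep(a, length(tt)), kalman_config(dt))
  i <- tt > 2
  expect_lt(max(abs(f$displacement[i] - x[i]) / pmax(x[i], 1e-9)), 0.001)
  expect_lt(max(abs(f$velocity[i] - v[i]) / pmax(v[i], 1e-9)), 0.001)
})

test_that("fusion beats differentiation of the noisy displacement", {
  set.seed(5)
  tt <- seq(0, 40, by = dt)
  x <- 0.01 * sin(2 * pi * 0.5 * tt)
  v <- 0.01 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * tt)
  a <- -0.01 * (2 * pi * 0.5)^2 * sin(2 * pi * 0.5 * tt)
  y <- x + rnorm(length(tt), 0, 0.001)       # 1 mm displacement noise
  u <- a + rnorm(length(tt), 0, 0.01)        # 10 mm/s^2 acceleration noise
  f <- kalman_fuse(y, u, kalman_config(dt))
  v_diff <- differentiate(y, fs)
  expect_lt(rmse_windowed(f$velocity, v, fs),
            rmse_windowed(v_diff, v, fs) / 2)
})

test_that("noise-free consistent input is tracked with <= 2 samples of lag", {
  tt <- seq(0, 40, by = dt)
  x <- 0.01 * sin(2 * pi * 1 * tt)
  a <- -0.01 * (2 * pi)^2 * sin(2 * pi * 1 * tt)
  f <- kalman_fuse(x, a, kalman_config(dt))
  i <- which(tt >= 5 & tt < 35)
  lags <- -5:5
  cc <- sapply(lags, function(l) cor(f$displacement[i], x[i - l]))
  expect_lte(abs(lags[which.max(cc)]), 2)
})

test_that("non-finite samples become flagged gaps, not silent values", {
  y <- sin(seq(0, 5, by = dt)); u <- numeric(length(y))
  y[100] <- NA
  expect_warning(f <- kalman_fuse(y, u, kalman_config(dt)), "gap")
  expect_true(is.na(f$displacement[100]))
  expect_false(anyNA(f$displacement[-100]))
  expect_equal(attr(f, "gaps"), 100L)
})

test_that("invalid configurations are rejected", {
  expect_error(kalman_config(dt, Q_w = matrix(c(1, 2, 0, 1), 2, 2)),
               "symmetric")
  expect_error(kalman_config(dt, Q_w = diag(c(-1, 1))), "semidefinite")
  expect_error(kalman_config(dt, Q_v = 0), "Q_v")
})
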