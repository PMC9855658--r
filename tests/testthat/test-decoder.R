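test_that("state model fitting recovers known dynamics", {
  # constant velocity: reproduced exactly with ~zero residual covariance
  vel <- matrix(rep(c(3, -2), each = 50), 50, 2)
  sm <- fit_state_model(vel)
  pred <- sm$A %*% c(3, -2, 1)
  expect_equal(as.numeric(pred), c(3, -2, 1), tolerance = 1e-9)
  expect_lt(max(abs(sm$W)), 1e-18)
  # offset element always maps to itself exactly
  expect_equal(sm$A[3, ], c(0, 0, 1))

  # AR(1) velocities with known coefficient: recovered within 5% at n = 2000
  set.seed(21)
  a_true <- 0.9
  n <- 2000
  v <- matrix(0, n, 2)
  for (k in 2:n) v[k, ] <- a_true * v[k - 1, ] + rnorm(2, sd = 0.5)
  sm2 <- fit_state_model(v)
  expect_lt(max(abs(diag(sm2$A[1:2, 1:2]) - a_true) / a_true), 0.05)
  expect_error(fit_state_model(v[1, , drop = FALSE]),
               class = "bcisim_invalid_parameter")
})

test_that("measurement model fitting is exact OLS with residual covariance", {
  set.seed(22)
  d <- 3; C <- 6; N <- 200
  x <- rbind(matrix(rnorm(2 * N), 2), 1)
  H0 <- cbind(matrix(rnorm(C * 2, sd = 2), C), runif(C, 5, 20))
  z <- H0 %*% x
  mm <- fit_measurement_model(z, x)
  expect_lt(max(abs(mm$H - H0)), 1e-8)
  expect_lt(max(abs(mm$Q)), 1e-12)

  # noisy case: Q recovered within 10% Frobenius at N = 5000
  N2 <- 5000
  x2 <- rbind(matrix(rnorm(2 * N2), 2), 1)
  L <- matrix(rnorm(C * C, sd = 0.3), C); Q0 <- crossprod(L) + diag(0.5, C)
  noise <- t(chol(Q0)) %*% matrix(rnorm(C * N2), C)
  mm2 <- fit_measurement_model(H0 %*% x2 + noise, x2)
  expect_lt(norm(mm2$Q - Q0, "F") / norm(Q0, "F"), 0.10)
  # the offset column absorbs baseline rate: residual means ~0
  res <- (H0 %*% x2 + noise) - mm2$H %*% x2
  expect_lt(max(abs(rowMeans(res))), 1e-8)

  bad <- rbind(matrix(rnorm(2 * 50), 2), 0)  # offset identically zero
  bad[2, ] <- 2 * bad[1, ]                   # collinear
  expect_error(fit_measurement_model(H0 %*% bad, bad),
               class = "bcisim_rank_error")
})

test_that("steady-state gain is the Riccati fixed point and matches the exact filter", {
  for (seed in 1:20) {
    model <- random_stable_model(seed)
    model <- steady_state_gain(model)
    # fixed point: one more Riccati step changes nothing
    Pm <- model$A %*% model$P %*% t(model$A) + model$W
    expect_lt(max(abs(Pm - model$P_prior)), 1e-9)
    # limit of the exact time-varying recursion
    tv <- time_varying_kalman(model$A, model$W, model$H,
                              model$Q + diag(1e-8 * mean(diag(model$Q)),
                                             nrow(model$Q)),
                              400, P0 = diag(c(1, 1, 0)))
    expect_lt(max(abs(tv$P_prior - model$P_prior)), 1e-8)
    expect_lt(max(abs(tv$K - model$K)), 1e-8)
  }
})

test_that("limit cases of the steady-state filter behave as expected", {
  # near-exact observation of the state: gain approaches identity on the
  # observed subspace and the filtered state approaches the observation
  A <- rbind(cbind(diag(0.5, 2), 0), c(0, 0, 1))
  W <- diag(c(1, 1, 0))
  H <- diag(1, 3)
  Q <- diag(1e-10, 3)
  m <- steady_state_gain(kalman_model(A, W, H, Q))
  expect_lt(max(abs(m$K[1:2, 1:2] - diag(1, 2))), 1e-3)

  # no state noise, stable dynamics: state fully predicted, K -> 0
  W0 <- matrix(0, 3, 3)
  m0 <- steady_state_gain(kalman_model(A, W0, H, diag(0.5, 3)))
  expect_lt(max(abs(m0$K)), 1e-4)
  tv <- time_varying_kalman(A, W0, H, diag(0.5, 3) + diag(1e-8 * 0.5, 3),
                            10000, P0 = diag(c(1, 1, 0)))
  expect_lt(max(abs(tv$K - m0$K)), 1e-6)
})

test_that("decode steps follow the innovation form", {
  model <- steady_state_gain(random_stable_model(31))
  st <- decoder_state(model)
  st$x <- c(2, -1, 1)
  # perfectly predicted observation: innovation zero, x = A x
  z_pred <- as.numeric(model$H %*% model$A %*% st$x)
  st2 <- decode_step(st, model, z_pred)
  expect_equal(st2$x[1:2], as.numeric(model$A %*% st$x)[1:2],
               tolerance = 1e-10)
  # K = 0: pure prediction regardless of z
  m0 <- model; m0$K <- m0$K * 0
  st3 <- decode_step(st, m0, rnorm(model$C))
  expect_equal(st3$x[1:2], as.numeric(model$A %*% st$x)[1:2],
               tolerance = 1e-12)
  # position integrates velocity over dt and offset stays 1
  expect_equal(st2$position, st$position + st2$x[1:2] * model$dt)
  expect_equal(st2$x[3], 1)
  expect_error(decode_step(st, model, rnorm(2)),
               class = "bcisim_shape_mismatch")
})

test_that("steady-state decoding matches a reference dense Kalman filter", {
  set.seed(33)
  model <- steady_state_gain(random_stable_model(12))
  C <- model$C
  # run both filters on the same observation stream
  st <- decoder_state(model)
  P <- diag(c(1, 1, 0))
  x_ref <- c(0, 0, 1)
  Qr <- model$Q + diag(1e-8 * mean(diag(model$Q)), C)
  err <- numeric(100)
  scale <- numeric(100)
  for (k in 1:100) {
    z <- rnorm(C, mean = 10)
    st <- decode_step(st, model, z)
    xp <- as.numeric(model$A %*% x_ref)
    Pm <- model$A %*% P %*% t(model$A) + model$W
    S <- model$H %*% Pm %*% t(model$H) + Qr
    K <- t(solve(S, model$H %*% Pm))
    x_ref <- xp + as.numeric(K %*% (z - model$H %*% xp))
    x_ref[3] <- 1
    P <- (diag(3) - K %*% model$H) %*% Pm
    err[k] <- max(abs(st$x[1:2] - x_ref[1:2]))
    scale[k] <- max(abs(x_ref[1:2]))
  }
  burn <- 30:100
  expect_lt(max(err[burn] / pmax(scale[burn], 1)), 0.01)
})

test_that("calibration recovers a planted measurement map in closed loop", {
  # emulated rates replaced by a noisy linear read of the reference state:
  # the fitted H matches and open-loop decoding tracks intended velocity
  set.seed(34)
  C <- 8
  H0 <- cbind(matrix(rnorm(C * 2, sd = 1.5), C), runif(C, 10, 30))
  N <- 600
  vel <- cbind(4 * sin(seq_len(N) / 30), 4 * cos(seq_len(N) / 40))
  x <- rbind(t(vel), 1)
  z <- H0 %*% x + matrix(rnorm(C * N, sd = 0.5), C)
  mm <- fit_measurement_model(z, x)
  expect_lt(max(abs(mm$H - H0)), 0.2)
  sm <- fit_state_model(vel)
  model <- steady_state_gain(kalman_model(sm$A, sm$W, mm$H, mm$Q))
  st <- decoder_state(model)
  dec <- matrix(0, N, 2)
  for (k in seq_len(N)) {
    st <- decode_step(st, model, z[, k])
    dec[k, ] <- st$x[1:2]
  }
  keep <- 50:N
  cs <- rowSums(dec[keep, ] * vel[keep, ]) /
    (sqrt(rowSums(dec[keep, ]^2)) * sqrt(rowSums(vel[keep, ]^2)))
  expect_gt(mean(cs, na.rm = TRUE), 0.7)
})
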