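# Shared fixtures and independent oracles. Everything here is deliberately
# simple and written independently of the package internals it checks.

# All permutations of 1..n, independent recursive enumeration.
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumerate_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Brute-force linear sum assignment: minimal total cost over all bijections.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in enumerate_perms(n)) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) best <- tot
  }
  best
}

# Exact time-varying Kalman filter (covariance recursion from P0), used as
# the oracle for the steady-state gain.
time_varying_kalman <- function(A, W, H, Q, n_steps, P0 = NULL) {
  d <- nrow(A)
  P <- if (is.null(P0)) diag(1, d) else P0
  K <- NULL
  for (i in seq_len(n_steps)) {
    Pm <- A %*% P %*% t(A) + W
    S <- H %*% Pm %*% t(H) + Q
    K <- t(solve(S, H %*% Pm))
    P <- (diag(d) - K %*% H) %*% Pm
  }
  list(K = K, P = P, P_prior = Pm)
}

# Random stable 3-state velocity-KF-shaped model (offset row fixed).
random_stable_model <- function(seed, C = 5) {
  set.seed(seed)
  A2 <- matrix(rnorm(4, sd = 0.3), 2)
  A2 <- A2 / max(abs(eigen(A2)$values)) * runif(1, 0.4, 0.9)
  A <- rbind(cbind(A2, 0), c(0, 0, 1))
  B <- matrix(rnorm(4, sd = 0.5), 2)
  W2 <- crossprod(B) + diag(0.05, 2)
  W <- matrix(0, 3, 3); W[1:2, 1:2] <- W2
  H <- cbind(matrix(rnorm(C * 2, sd = 2), C), rnorm(C, 5, 2))
  Bq <- matrix(rnorm(C * C, sd = 0.4), C)
  Q <- crossprod(Bq) + diag(0.2, C)
  kalman_model(A, W, H, Q)
}

# Tiny emulator setup used by the unit tests (fast to train).
tiny_config <- function() {
  emulator_config(n_lags = 2, n_sensors = 3, encoder_widths = c(8, 6, 4),
                  readout_hidden_width = 3)
}

# Neural trials tibble from a list of rate matrices (helper to build
# hand-made sessions).
as_neural_trials <- function(mats, conditions, time = NULL) {
  out <- tibble::tibble(session_id = "T", trial_id = seq_along(mats),
                        condition = conditions, rates = mats)
  if (!is.null(time)) attr(out, "time") <- time
  class(out) <- c("neural_trials", class(out))
  out
}

# Planted planar rotation embedded in 6D (with faint off-plane components so
# the 6D PCA is well defined), one trial per condition.
planted_rotation_trials <- function(omega, n_cond = 8, dt = 0.025,
                                    n_steps = 40, seed = 1,
                                    off_plane = 1e-3) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(36), 6)))
  tg <- dt * (seq_len(n_steps) - 1)
  mats <- lapply(seq_len(n_cond), function(cc) {
    ph <- 2 * pi * cc / n_cond
    xy <- rbind(cos(ph + omega * tg), sin(ph + omega * tg))
    extra <- off_plane * rbind(cos(2 * ph + 0.5 * omega * tg),
                               sin(2 * ph + 0.5 * omega * tg),
                               cos(3 * ph + 0.2 * omega * tg),
                               sin(3 * ph + 0.2 * omega * tg))
    U %*% rbind(xy, extra) + 10
  })
  as_neural_trials(mats, seq_len(n_cond), time = tg)
}

# Default-conditions study data at the criterion scale (3 sessions x
# 20 trials/condition, 4 replicated kinematic subjects).
default_study_data <- function(seed) {
  simulate_study_data(experiment_config(seed = seed))
}

# Desk-scale training control used by the acceptance checks.
acceptance_control <- function() {
  emulator_control(steps_per_visit = 700, max_rounds = 8, lr = 6e-3,
                   lr_decay = 0.85, polish_steps = 2000)
}
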