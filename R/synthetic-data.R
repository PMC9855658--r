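#' Specify a synthetic neural recording session
#'
#' A session mimics one day of simultaneous single-neuron recordings from the
#' arm area of primary motor cortex during an 8-direction center-out task:
#' between 23 and 93 neurons, trials segmented from 200 ms before to 800 ms
#' after the go cue, firing rates on a 25 ms grid (40 samples per trial).
#'
#' @param session_id Character label for the session.
#' @param n_neurons Number of simultaneously recorded neurons (23-93 in the
#'   data this emulates; any count >= 1 is accepted).
#' @param n_trials_per_condition Trials per reach condition (default 20, a
#'   desk-scale count; recorded sessions ranged from 163 to 1037 trials total).
#' @param n_conditions Number of reach conditions (default 8).
#' @param dt Sample period in seconds (default 0.025).
#' @param t_start,t_end Trial window relative to the go cue, seconds.
#' @param seed Integer seed controlling every random draw for this session.
#'
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(session_id = "S01", n_neurons = 45,
                         n_trials_per_condition = 20, n_conditions = 8,
                         dt = 0.025, t_start = -0.2, t_end = 0.8, seed = 1L) {
  check_number(n_neurons, "n_neurons", lower = 1, integer = TRUE)
  check_number(n_trials_per_condition, "n_trials_per_condition", lower = 1,
               integer = TRUE)
  check_number(n_conditions, "n_conditions", lower = 2, integer = TRUE)
  check_number(dt, "dt", lower = 1e-9)
  n_steps <- round((t_end - t_start) / dt)
  if (abs((t_end - t_start) / dt - n_steps) > 1e-9) {
    stop_bcisim("trial window must be an integer number of dt steps",
                "bcisim_invalid_parameter")
  }
  structure(
    list(session_id = session_id, n_neurons = as.integer(n_neurons),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         n_conditions = as.integer(n_conditions), dt = dt,
         t_start = t_start, t_end = t_end, n_steps = as.integer(n_steps),
         time = t_start + dt * seq(0, n_steps - 1L), seed = as.integer(seed)),
    class = "session_spec"
  )
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf(
    "<session_spec %s: %d neurons, %d conditions x %d trials, %d steps @ %g s>\n",
    x$session_id, x$n_neurons, x$n_conditions, x$n_trials_per_condition,
    x$n_steps, x$dt))
  invisible(x)
}

#' Smooth spike trains into firing rates
#'
#' Convolves spike event times with a unit-mass Gaussian kernel of total
#' duration 100 ms (SD 25 ms, truncated at +/-2 SD and renormalised so each
#' spike contributes unit mass) and evaluates the resulting rate on the
#' session's 25 ms grid. With unit-mass kernels the time integral of the rate
#' over the window matches the spike count for spikes away from the edges.
#'
#' @param spike_times List with one numeric vector of spike times (seconds,
#'   same clock as the session window) per neuron. An empty vector yields an
#'   all-zero rate trace.
#' @param spec A [session_spec()].
#' @param kernel_sd Gaussian kernel SD in seconds (default 0.025; the kernel
#'   support is `4 * kernel_sd`, i.e. 100 ms at the default).
#'
#' @return Matrix of firing rates, `n_neurons x n_steps`, spikes/s.
#' @export
smooth_spike_trains <- function(spike_times, spec, kernel_sd = 0.025) {
  stopifnot(inherits(spec, "session_spec"))
  if (!is.numeric(kernel_sd) || length(kernel_sd) != 1L || kernel_sd <= 0) {
    stop_bcisim("`kernel_sd` must be a positive number",
                "bcisim_invalid_parameter")
  }
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  tgrid <- spec$time
  dt <- spec$dt
  # CDF of the +/-2 SD truncated, unit-mass kernel; each 25 ms bin receives
  # the exact kernel mass falling inside it, so the rate integral over the
  # window equals the spike count for spikes away from the edges
  mass <- stats::pnorm(2) - stats::pnorm(-2)
  kcdf <- function(u) {
    pmin(pmax((stats::pnorm(u / kernel_sd) - stats::pnorm(-2)) / mass, 0), 1)
  }
  rates <- vapply(spike_times, function(st) {
    if (length(st) == 0L) return(numeric(length(tgrid)))
    r <- numeric(length(tgrid))
    for (s in st) {
      u <- tgrid - s
      r <- r + (kcdf(u + dt / 2) - kcdf(u - dt / 2)) / dt
    }
    r
  }, numeric(length(tgrid)))
  t(rates)
}

# Skew-symmetric block-diagonal latent dynamics: planes rotating at
# omega, omega/3, omega/5, ... (one frequency per plane).
latent_dynamics_matrix <- function(latent_dim, rotation_strength) {
  M <- matrix(0, latent_dim, latent_dim)
  n_planes <- latent_dim %/% 2
  for (p in seq_len(n_planes)) {
    w <- rotation_strength / (2 * p - 1)
    i <- 2 * p - 1
    M[i, i + 1] <- -w
    M[i + 1, i] <- w
  }
  M
}

# Closed-form evolution of x0 under the block-rotation dynamics above.
evolve_latent <- function(x0, rotation_strength, tgrid) {
  d <- length(x0)
  out <- matrix(0, d, length(tgrid))
  for (p in seq_len(d %/% 2)) {
    w <- rotation_strength / (2 * p - 1)
    i <- 2 * p - 1
    ct <- cos(w * tgrid); st <- sin(w * tgrid)
    out[i, ] <- ct * x0[i] - st * x0[i + 1]
    out[i + 1, ] <- st * x0[i] + ct * x0[i + 1]
  }
  if (d %% 2 == 1L) out[d, ] <- x0[d]
  out
}

#' Generate a synthetic motor-cortex session
#'
#' Emulates the population structure the downstream pipeline assumes:
#' a low-dimensional latent trajectory obeying skew-symmetric (rotational)
#' linear dynamics, with the reach condition setting the initial phase on the
#' dominant plane (`2*pi*c / n_conditions`), read out into non-negative firing
#' rates through a per-session random map `softplus(B x + b0)`. Trial-to-trial
#' variability is injected in latent space (a random offset to the latent
#' initial condition, evolved under the same dynamics) so that rate variation
#' is correlated across neurons rather than channel-independent.
#'
#' @param spec A [session_spec()].
#' @param latent_dim Latent dimensionality (even, >= 2; default 6).
#' @param rotation_strength Angular frequency of the dominant latent plane,
#'   rad/s (default `2*pi`, one rotation cycle per second).
#' @param latent_noise_sd SD of the per-trial latent initial-condition offset
#'   (default 0.08; the dominant plane has unit amplitude).
#'
#' @return A tibble of class `neural_trials`: one row per trial with columns
#'   `session_id`, `trial_id`, `condition` and a list-column `rates`
#'   (`n_neurons x n_steps` matrices, spikes/s). The time base, generator
#'   parameters and true condition phases are attached as attributes.
#' @export
generate_neural_session <- function(spec, latent_dim = 6,
                                    rotation_strength = 2 * pi,
                                    latent_noise_sd = 0.08) {
  stopifnot(inherits(spec, "session_spec"))
  check_number(latent_dim, "latent_dim", lower = 2, integer = TRUE)
  check_number(rotation_strength, "rotation_strength", lower = 1e-9)
  if (spec$n_neurons < 1) {
    stop_bcisim("n_neurons must be >= 1", "bcisim_invalid_parameter")
  }

  # plane amplitudes decay so the top plane dominates
  n_planes <- latent_dim %/% 2
  amp <- 0.4^(seq_len(n_planes) - 1)

  set.seed(spec$seed)
  B <- matrix(rnorm(spec$n_neurons * latent_dim, sd = 8), spec$n_neurons)
  b0 <- runif(spec$n_neurons, 10, 25)
  phases <- 2 * pi * seq_len(spec$n_conditions) / spec$n_conditions

  tgrid <- spec$time - spec$t_start  # dynamics clock starts at trial start
  rows <- list()
  trial_id <- 0L
  for (cond in seq_len(spec$n_conditions)) {
    x0_base <- numeric(latent_dim)
    for (p in seq_len(n_planes)) {
      ph <- phases[cond] * p  # harmonics of the condition phase per plane
      x0_base[2 * p - 1] <- amp[p] * cos(ph)
      x0_base[2 * p] <- amp[p] * sin(ph)
    }
    for (r in seq_len(spec$n_trials_per_condition)) {
      trial_id <- trial_id + 1L
      delta <- rnorm(latent_dim, sd = latent_noise_sd)
      x <- evolve_latent(x0_base + delta, rotation_strength, tgrid)
      rates <- softplus(B %*% x + b0)
      rows[[trial_id]] <- tibble(
        session_id = spec$session_id, trial_id = trial_id,
        condition = cond, rates = list(rates)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "time") <- spec$time
  attr(out, "spec") <- spec
  attr(out, "generator") <- list(latent_dim = latent_dim,
                                 rotation_strength = rotation_strength,
                                 latent_noise_sd = latent_noise_sd,
                                 phases = phases, B = B, b0 = b0)
  class(out) <- c("neural_trials", class(out))
  out
}

#' Define the posture set for the 8 finger movements
#'
#' Builds a rest posture and 8 target postures in normalized 19-sensor glove
#' coordinates. The targets are arranged on a ring in a random 2D plane of
#' sensor space (plus small off-plane structure), so that generated trials
#' project to 8 distinct clusters arranged in a ring on the top-2 PCA plane,
#' mirroring the geometry of the neural data.
#'
#' @param seed Integer seed.
#' @param n_targets Number of target postures (default 8).
#' @param ring_radius Ring radius in normalized sensor units (default 0.25).
#' @param motor_noise_sd Per-sensor SD of the smooth motor noise added to
#'   each repetition (default 0.02 normalized units).
#'
#' @return Object of class `posture_set` with fields `rest` (19-vector),
#'   `targets` (`n_targets x 19`), `directions` (the ring angle assigned to
#'   each posture, radians) and `motor_noise_sd`.
#' @export
posture_set <- function(seed = 1L, n_targets = 8, ring_radius = 0.25,
                        motor_noise_sd = 0.02) {
  check_number(n_targets, "n_targets", lower = 2, integer = TRUE)
  set.seed(seed)
  n_sensors <- 19L
  rest <- runif(n_sensors, 0.35, 0.55)
  # orthonormal ring plane in sensor space
  u <- qr.Q(qr(matrix(rnorm(n_sensors * 2), n_sensors)))
  ang <- 2 * pi * seq_len(n_targets) / n_targets
  targets <- t(vapply(seq_len(n_targets), function(j) {
    off <- rnorm(n_sensors, sd = 0.03)  # mild off-plane idiosyncrasy
    p <- rest + ring_radius * (cos(ang[j]) * u[, 1] + sin(ang[j]) * u[, 2]) + off
    pmin(pmax(p, 0.02), 0.98)
  }, numeric(n_sensors)))
  structure(
    list(rest = rest, targets = targets, directions = ang,
         motor_noise_sd = motor_noise_sd, seed = as.integer(seed)),
    class = "posture_set"
  )
}

# Smooth (low-pass filtered) Gaussian noise, one row per sensor; a burn-in
# brings the filter to its stationary distribution before the trial starts.
smooth_noise <- function(n_sensors, n_steps, sd, dt, tau = 0.1) {
  if (sd <= 0) return(matrix(0, n_sensors, n_steps))
  burn <- 50L
  total <- n_steps + burn
  w <- matrix(rnorm(n_sensors * total), n_sensors)
  a <- dt / (tau + dt)
  out <- matrix(0, n_sensors, total)
  out[, 1] <- w[, 1] * sqrt(a / (2 - a))   # stationary EMA variance
  for (k in 2:total) out[, k] <- (1 - a) * out[, k - 1] + a * w[, k]
  out <- out[, (burn + 1):total, drop = FALSE]
  # rescale to the requested marginal SD
  s <- sd(as.numeric(out))
  if (s > 0) out <- out * (sd / s)
  out
}

#' Generate repeated glove-like finger movement trials
#'
#' Each trial is a minimum-jerk transition from the rest posture to a target
#' posture over `duration` seconds on a `dt` grid, with smooth (low-pass
#' filtered Gaussian) motor noise added per repetition and values clipped to
#' the normalized sensor range \[0, 1\].
#'
#' @param postures A [posture_set()].
#' @param n_reps Repetitions per condition (default 20).
#' @param duration Movement duration, seconds (default 1.2).
#' @param dt Sample period, seconds (default 0.025).
#' @param seed Integer seed.
#' @param subject_id Label stored with each trial.
#'
#' @return A tibble of class `kinematic_trials`: one row per trial with
#'   columns `subject_id`, `trial_id`, `condition` and a list-column
#'   `sensors` (`19 x n_steps` matrices). Time base attached as attribute.
#' @export
generate_kinematic_trials <- function(postures, n_reps = 20, duration = 1.2,
                                      dt = 0.025, seed = 1L,
                                      subject_id = "P01") {
  stopifnot(inherits(postures, "posture_set"))
  check_number(n_reps, "n_reps", lower = 1, integer = TRUE)
  check_number(duration, "duration", lower = 1e-9)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop_bcisim("`dt` must be a positive number", "bcisim_invalid_parameter")
  }
  set.seed(seed)
  tgrid <- seq(0, duration, by = dt)
  tau <- tgrid / duration
  prof <- min_jerk(tau)
  n_targets <- nrow(postures$targets)
  n_sensors <- length(postures$rest)

  rows <- list()
  trial_id <- 0L
  for (cond in seq_len(n_targets)) {
    delta <- postures$targets[cond, ] - postures$rest
    clean <- postures$rest + outer(delta, prof)  # sensors x steps
    for (r in seq_len(n_reps)) {
      trial_id <- trial_id + 1L
      noise <- smooth_noise(n_sensors, length(tgrid), postures$motor_noise_sd,
                            dt)
      s <- pmin(pmax(clean + noise, 0), 1)
      rows[[trial_id]] <- tibble(
        subject_id = subject_id, trial_id = trial_id, condition = cond,
        sensors = list(s)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "time") <- tgrid
  attr(out, "postures") <- postures
  class(out) <- c("kinematic_trials", class(out))
  out
}

#' Resample a trial matrix to a new number of steps
#'
#' Linear interpolation in normalized time; used to align 1.2 s kinematic
#' trials with the 40-step neural window when pairing or training.
#'
#' @param mat Channels-by-time matrix.
#' @param n_steps_out Target number of time steps.
#' @return Channels-by-`n_steps_out` matrix.
#' @export
resample_trial <- function(mat, n_steps_out) {
  n_in <- ncol(mat)
  if (n_in == n_steps_out) return(mat)
  xin <- seq(0, 1, length.out = n_in)
  xout <- seq(0, 1, length.out = n_steps_out)
  t(apply(mat, 1, function(r) stats::approx(xin, r, xout)$y))
}
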