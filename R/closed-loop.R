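#' Center-out task configuration
#'
#' Defaults follow the standard 4-target center-out cursor protocol: a
#' 31 x 31 cm workspace, 1.3 cm cursor radius, 5 x 5 cm targets with a 0.3 cm
#' border, 500 ms dwell to register a hit, 7 s timeout, 80 trials per visit
#' at a 25 ms tick. The target distance is set so the Fitts index of
#' difficulty `log2(D/W + 1)` (Shannon form) equals 1.2, giving
#' `D = 5 * (2^1.2 - 1) ~ 6.49 cm`. The 6.5 s error-rate threshold and the
#' 7 s timeout are kept as two distinct constants.
#'
#' @param workspace Workspace side length, cm.
#' @param cursor_radius Cursor radius, cm.
#' @param target_size Target side length, cm.
#' @param target_border Target border thickness, cm.
#' @param dwell Required continuous in-target time, s.
#' @param timeout Trial timeout, s.
#' @param n_targets Number of peripheral targets.
#' @param trials_per_visit Center-out trials per visit.
#' @param tick Control loop period, s.
#' @param er_threshold Error-rate time criterion, s.
#' @param fitts_id Fitts index of difficulty fixing the target distance.
#' @param hit_rule `"center"` (cursor center inside the target square,
#'   default) or `"overlap"` (cursor disc overlaps the square).
#' @return Object of class `task_config`.
#' @export
task_config <- function(workspace = 31, cursor_radius = 1.3, target_size = 5,
                        target_border = 0.3, dwell = 0.5, timeout = 7,
                        n_targets = 4, trials_per_visit = 80, tick = 0.025,
                        er_threshold = 6.5, fitts_id = 1.2,
                        hit_rule = c("center", "overlap")) {
  stopifnot(dwell < timeout, tick > 0)
  hit_rule <- match.arg(hit_rule)
  target_distance <- target_size * (2^fitts_id - 1)
  structure(list(workspace = workspace, cursor_radius = cursor_radius,
                 target_size = target_size, target_border = target_border,
                 dwell = dwell, timeout = timeout,
                 n_targets = as.integer(n_targets),
                 trials_per_visit = as.integer(trials_per_visit), tick = tick,
                 er_threshold = er_threshold, fitts_id = fitts_id,
                 target_distance = target_distance, hit_rule = hit_rule),
            class = "task_config")
}

#' Peripheral target positions
#' @param config A [task_config()].
#' @return `n_targets x 2` matrix of target centers (cm from workspace center).
#' @export
target_positions <- function(config) {
  ang <- 2 * pi * (seq_len(config$n_targets) - 1) / config$n_targets
  cbind(x = config$target_distance * cos(ang),
        y = config$target_distance * sin(ang))
}

# Posture condition whose calibration direction matches a target angle.
posture_for_angle <- function(angle, postures) {
  which.min(abs(atan2(sin(postures$directions - angle),
                      cos(postures$directions - angle))))
}

in_target <- function(pos, target, config) {
  half <- config$target_size / 2
  inside <- abs(pos[1] - target[1]) <= half & abs(pos[2] - target[2]) <= half
  if (config$hit_rule == "overlap") {
    dx <- pmax(abs(pos[1] - target[1]) - half, 0)
    dy <- pmax(abs(pos[2] - target[2]) - half, 0)
    inside <- sqrt(dx^2 + dy^2) <= config$cursor_radius
  }
  inside
}

new_lag_buffer <- function(rest, n_lags = 4) {
  matrix(rest, length(rest), n_lags + 1)
}

push_lag_buffer <- function(buf, sample) {
  cbind(sample, buf[, -ncol(buf), drop = FALSE])
}

#' Greedy simulated user
#'
#' Stands in for the human subject: at each tick it blends the target
#' postures whose calibration directions align with the desired cursor
#' direction `d = unit(target - cursor)`, with weights
#' `w_j = max(0, cos(angle(d, dir_j)))^p` (normalized), low-pass filters the
#' command with time constant `tau`, adds Gaussian motor noise and clips to
#' \[0, 1\]. On target (direction undefined) the command decays to rest.
#'
#' @param postures A [posture_set()].
#' @param gain Scales the posture deviation from rest (default 1).
#' @param noise_sd Motor noise SD, normalized sensor units (default the
#'   posture set's `motor_noise_sd`).
#' @param tau First-order smoothing time constant, s (default 0.15).
#' @param p Directional sharpness exponent (default 4).
#' @param deadzone Distance to target below which the user relaxes to rest,
#'   cm (default 1).
#' @return Object of class `user_policy`; call `policy$step(cursor, target,
#'   dt)` for the next 19-sensor posture sample and `policy$reset()` between
#'   trials.
#' @export
simulated_user_policy <- function(postures, gain = 1,
                                  noise_sd = postures$motor_noise_sd,
                                  tau = 0.15, p = 4, deadzone = 1) {
  state <- new.env(parent = emptyenv())
  state$s <- postures$rest
  step <- function(cursor, target, dt = 0.025) {
    d <- target - cursor
    dist <- sqrt(sum(d^2))
    if (dist < deadzone) {
      cmd <- postures$rest
    } else {
      ang <- atan2(d[2], d[1])
      w <- pmax(0, cos(postures$directions - ang))^p
      if (sum(w) < .Machine$double.eps) {
        cmd <- postures$rest
      } else {
        w <- w / sum(w)
        dev <- colSums(w * sweep(postures$targets, 2, postures$rest))
        cmd <- postures$rest + gain * dev
      }
    }
    a <- dt / (tau + dt)
    state$s <- state$s + a * (cmd - state$s)
    out <- state$s + rnorm(length(cmd), sd = noise_sd)
    pmin(pmax(out, 0), 1)
  }
  reset <- function() state$s <- postures$rest
  structure(list(step = step, reset = reset, postures = postures,
                 gain = gain, noise_sd = noise_sd, tau = tau, p = p),
            class = "user_policy")
}

# Paced calibration movement: rest -> target posture, minimum jerk over
# `duration`, sampled at ticks dt, 2dt, ..., duration.
calibration_movement <- function(postures, cond, duration = 1.5, dt = 0.025,
                                 noise_sd = postures$motor_noise_sd) {
  tgrid <- seq(dt, duration, by = dt)
  prof <- min_jerk(tgrid / duration)
  delta <- postures$targets[cond, ] - postures$rest
  clean <- postures$rest + outer(delta, prof)
  noise <- smooth_noise(length(postures$rest), length(tgrid), noise_sd, dt)
  pmin(pmax(clean + noise, 0), 1)
}

#' Six-block decoder calibration
#'
#' Reproduces the standard calibration protocol: six 30-trial blocks of paced
#' 1.5 s posture transitions toward displayed targets. The reference
#' ("intended") velocity is always the velocity of the pre-defined
#' straight-line center-to-target trajectory (minimum-jerk speed profile).
#' During blocks 1-2 the user only observes the ideal cursor; the state model
#' (A, W) is fit from the reference velocities and the measurement model
#' (H, Q) from the accumulated (rates, reference-state) pairs. During blocks
#' 3-6 the decoded cursor is also shown and (H, Q) are refit after each block
#' on all data so far.
#'
#' @param net A trained `emulator_net` with the visit's session active.
#' @param postures The [posture_set()] the user executes.
#' @param config A [task_config()].
#' @param seed Integer seed (target order, motor noise).
#' @param n_blocks,trials_per_block Calibration protocol size (6 x 30).
#' @param transition_duration Paced movement duration, s (default 1.5).
#' @return A [kalman_model()] with steady-state gain computed. The attribute
#'   `"calibration_log"` holds a per-trial tibble (block, trial, target
#'   condition, mode) and `"calibration_data"` the block-6 open-loop decode
#'   for diagnostics.
#' @export
run_calibration <- function(net, postures, config = task_config(), seed = 1L,
                            n_blocks = 6, trials_per_block = 30,
                            transition_duration = 1.5) {
  set.seed(seed)
  tp <- target_positions(config)
  n_t <- nrow(tp)
  conds <- vapply(seq_len(n_t), function(i) {
    posture_for_angle(atan2(tp[i, 2], tp[i, 1]), postures)
  }, integer(1))
  dt <- config$tick
  tgrid <- seq(dt, transition_duration, by = dt)
  n_ticks <- length(tgrid)

  Z_all <- NULL
  X_all <- NULL
  vel_trials <- list()
  log_rows <- list()
  model <- NULL
  block6 <- NULL

  for (b in seq_len(n_blocks)) {
    targets_b <- sample(rep(seq_len(n_t), length.out = trials_per_block))
    mode <- if (b <= 2) "observation" else "assisted"
    Z_block <- NULL
    vel_block <- NULL
    for (tr in seq_along(targets_b)) {
      ti <- targets_b[tr]
      dir <- tp[ti, ] / sqrt(sum(tp[ti, ]^2))
      # reference straight-line trajectory with minimum-jerk speed profile
      speed <- config$target_distance *
        min_jerk_deriv(tgrid / transition_duration) / transition_duration
      vel <- cbind(speed * dir[1], speed * dir[2])
      kin <- calibration_movement(postures, conds[ti], transition_duration,
                                  dt, postures$motor_noise_sd)
      Z <- emulate_trial(net, kin)            # C x n_ticks
      Z_all <- cbind(Z_all, Z)
      X_all <- cbind(X_all, rbind(t(vel), 1))
      vel_trials[[length(vel_trials) + 1]] <- vel
      Z_block <- cbind(Z_block, Z)
      vel_block <- rbind(vel_block, vel)
      log_rows[[length(log_rows) + 1]] <- tibble(
        block = b, trial = tr, target = ti, condition = conds[ti],
        mode = mode)
    }
    if (b == n_blocks) block6 <- list(Z = Z_block, vel = vel_block)
    if (b >= 2) {
      sm <- fit_state_model(vel_trials)
      mm <- fit_measurement_model(Z_all, X_all)
      model <- steady_state_gain(
        kalman_model(sm$A, sm$W, mm$H, mm$Q, dt = dt))
    }
  }
  attr(model, "calibration_log") <- dplyr::bind_rows(log_rows)
  attr(model, "calibration_data") <- block6
  attr(model, "session_id") <- net$active_session
  model
}

#' Run one closed-loop center-out trial
#'
#' Loops at the 25 ms tick: sample the user's posture, update the lag buffer,
#' emulate firing rates, decode one Kalman step, clamp the cursor to the
#' workspace, and apply the dwell/timeout rules. The dwell counter resets
#' fully on target exit. After the trial outcome, an untimed return-to-center
#' phase runs until the cursor is within 1 cm of the center (with a 30 s
#' failsafe after which the cursor is recentered).
#'
#' @param policy A [simulated_user_policy()] (or any object with a
#'   `step(cursor, target, dt)` function returning a 19-vector).
#' @param net Trained `emulator_net`, active session matching the decoder.
#' @param model Calibrated [kalman_model()] with gain.
#' @param state A [decoder_state()]; persists across trials within a visit.
#' @param buf Lag buffer from [new_lag_buffer()]; persists across trials.
#' @param config A [task_config()].
#' @param target Target center, length-2 (cm).
#' @param return_to_center Run the inter-trial recentering phase (default
#'   TRUE).
#' @return List with `log` (per-tick tibble: t, sensor matrix row index,
#'   decoded velocity, cursor position, in-target flag), `sensors` and
#'   `rates` matrices, `outcome` ("hit"/"miss"), `movement_time` (s, NA for a
#'   miss), `tick_compute` (mean seconds of compute per tick), and the
#'   updated `state` and `buf`.
#' @export
run_trial <- function(policy, net, model, state, buf, config, target,
                      return_to_center = TRUE) {
  dt <- config$tick
  n_max <- round(config$timeout / dt)
  ns <- nrow(buf)
  sensors <- matrix(NA_real_, ns, n_max)
  rates <- matrix(NA_real_, model$C, n_max)
  pos <- matrix(NA_real_, n_max, 2)
  velo <- matrix(NA_real_, n_max, 2)
  inside <- logical(n_max)
  dwell_ticks_needed <- round(config$dwell / dt)
  dwell <- 0L
  outcome <- "miss"
  mt <- NA_real_
  half_ws <- config$workspace / 2
  k_end <- n_max
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(n_max)) {
    s <- policy$step(state$position, target, dt)
    buf <- push_lag_buffer(buf, s)
    z <- forward(net, as.numeric(buf))
    state <- decode_step(state, model, z)
    state$position <- pmin(pmax(state$position, -half_ws), half_ws)
    sensors[, k] <- s
    rates[, k] <- z
    pos[k, ] <- state$position
    velo[k, ] <- state$x[1:2]
    inside[k] <- in_target(state$position, target, config)
    dwell <- if (inside[k]) dwell + 1L else 0L
    # dwell time elapsed since target entry: (consecutive ticks - 1) * dt
    if (dwell > dwell_ticks_needed) {
      outcome <- "hit"
      mt <- k * dt
      k_end <- k
      break
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  keep <- seq_len(k_end)
  log <- tibble(t = keep * dt, x = pos[keep, 1], y = pos[keep, 2],
                vx = velo[keep, 1], vy = velo[keep, 2],
                in_target = inside[keep])
  if (return_to_center) {
    for (k in seq_len(round(30 / dt))) {
      s <- policy$step(state$position, c(0, 0), dt)
      buf <- push_lag_buffer(buf, s)
      z <- forward(net, as.numeric(buf))
      state <- decode_step(state, model, z)
      state$position <- pmin(pmax(state$position, -half_ws), half_ws)
      if (sqrt(sum(state$position^2)) < 1) break
    }
    if (sqrt(sum(state$position^2)) >= 1) state$position <- c(0, 0)
  }
  list(log = log, sensors = sensors[, keep, drop = FALSE],
       rates = rates[, keep, drop = FALSE], outcome = outcome,
       movement_time = mt, tick_compute = elapsed / k_end,
       state = state, buf = buf)
}

#' Plan a subject's visits
#'
#' Assigns each visit a session (sampled without replacement within the
#' subject) so no session repeats across a subject's visits, mimicking the
#' day-to-day turnover of recorded neuron sets.
#'
#' @param subject_id Subject label.
#' @param session_ids Available emulator session ids.
#' @param n_visits Number of visits (default 4).
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `visit`, `session_id`, `seed` per visit.
#' @export
visit_plan <- function(subject_id, session_ids, n_visits = 4, seed = 1L) {
  if (n_visits > length(session_ids)) {
    stop_bcisim("not enough sessions to avoid repeats within a subject",
                "bcisim_invalid_parameter")
  }
  set.seed(seed)
  tibble(subject_id = subject_id, visit = seq_len(n_visits),
         session_id = sample(session_ids, n_visits),
         seed = seed + seq_len(n_visits))
}

#' Run one closed-loop visit
#'
#' Activates the planned session, runs the six-block calibration, then the
#' visit's center-out trials with targets in seeded, balanced random order.
#'
#' @param net Trained `emulator_net` covering the planned session.
#' @param session_id Session to activate.
#' @param postures The [posture_set()].
#' @param config A [task_config()].
#' @param seed Integer seed for calibration and trial order.
#' @param policy Optional user policy (default a [simulated_user_policy()]).
#' @param keep_signals Keep per-tick sensor/rate matrices in the output
#'   (default FALSE to save memory).
#' @param n_blocks,trials_per_block Calibration protocol size (default 6 x 30).
#' @return List with `trials` (one row per trial: target, outcome,
#'   movement_time, trajectory list-column, per-trial metrics), `summary`
#'   (one-row tibble of visit-level measures) and `model` (the calibrated
#'   decoder).
#' @export
run_visit <- function(net, session_id, postures, config = task_config(),
                      seed = 1L, policy = NULL, keep_signals = FALSE,
                      n_blocks = 6, trials_per_block = 30) {
  net <- set_active_session(net, session_id)
  model <- run_calibration(net, postures, config, seed = seed,
                           n_blocks = n_blocks,
                           trials_per_block = trials_per_block)
  set.seed(seed + 1L)
  if (is.null(policy)) policy <- simulated_user_policy(postures)
  tp <- target_positions(config)
  n_t <- nrow(tp)
  stopifnot(config$trials_per_visit %% n_t == 0)
  order_t <- sample(rep(seq_len(n_t), config$trials_per_visit / n_t))
  state <- decoder_state(model)
  buf <- new_lag_buffer(postures$rest, net$config$n_lags)
  rows <- vector("list", length(order_t))
  for (i in seq_along(order_t)) {
    ti <- order_t[i]
    res <- run_trial(policy, net, model, state, buf, config, tp[ti, ])
    state <- res$state
    buf <- res$buf
    m <- trial_metrics(cbind(res$log$x, res$log$y), c(0, 0), tp[ti, ],
                       outcome = res$outcome,
                       movement_time = res$movement_time,
                       dt = config$tick)
    rows[[i]] <- dplyr::bind_cols(
      tibble(trial = i, target = ti, outcome = res$outcome,
             movement_time = res$movement_time,
             tick_compute = res$tick_compute,
             trajectory = list(cbind(res$log$x, res$log$y))),
      m,
      if (keep_signals) tibble(sensors = list(res$sensors),
                               rates = list(res$rates)))
  }
  trials <- dplyr::bind_rows(rows)
  summary <- tibble(
    session_id = session_id,
    n_trials = nrow(trials),
    hits = sum(trials$outcome == "hit"),
    hit_rate = mean(trials$outcome == "hit"),
    ER = error_rate(trials, config$er_threshold),
    MT = mean(trials$movement_time[trials$outcome == "hit"]),
    ME = mean(trials$ME), MV = mean(trials$MV),
    MDC = mean(trials$MDC), ODC = mean(trials$ODC),
    DR = mean(trials$DR, na.rm = TRUE),
    tick_compute = mean(trials$tick_compute)
  )
  list(trials = trials, summary = summary, model = model)
}
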