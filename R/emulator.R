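#' Emulator architecture configuration
#'
#' The firing-rate emulator is a time-delay neural network: the current
#' 19-sensor glove sample plus four 25 ms lags (95 inputs) feed a shared
#' kinematics encoder of three tanh layers (150, 100, 50 units) whose
#' 50-dimensional output is a latent space of characteristic neural
#' activations. A session-specific readout module (tanh hidden layer of 30
#' units, rectified-linear output layer sized to that session's neuron count)
#' maps the latent space to firing rates. All layers carry biases.
#'
#' @param n_lags Number of time delays in addition to the current sample
#'   (default 4, i.e. 5 taps spanning 100 ms).
#' @param n_sensors Glove channels (default 19).
#' @param encoder_widths Hidden widths of the shared encoder.
#' @param readout_hidden_width Hidden width of each session readout.
#' @param dt Tick period, seconds.
#' @return Object of class `emulator_config`.
#' @export
emulator_config <- function(n_lags = 4, n_sensors = 19,
                            encoder_widths = c(150, 100, 50),
                            readout_hidden_width = 30, dt = 0.025) {
  check_number(n_lags, "n_lags", lower = 0, integer = TRUE)
  stopifnot(all(encoder_widths >= 1), readout_hidden_width >= 1)
  structure(
    list(n_lags = as.integer(n_lags), n_sensors = as.integer(n_sensors),
         input_dim = as.integer(n_sensors * (n_lags + 1)),
         encoder_widths = as.integer(encoder_widths),
         readout_hidden_width = as.integer(readout_hidden_width), dt = dt),
    class = "emulator_config"
  )
}

#' Build the lagged input vector at one time step
#'
#' Concatenates the kinematic samples at steps `t, t-1, ..., t-n_lags` (most
#' recent first). Lags that precede the start of the series are filled with
#' the series' first sample, so trial-start inputs see a constant history.
#'
#' @param kin_series Channels-by-time matrix.
#' @param t Step index, 1-based.
#' @param n_lags Number of lags (default 4).
#' @return Numeric vector of length `channels * (n_lags + 1)`.
#' @export
build_lagged_input <- function(kin_series, t, n_lags = 4) {
  if (t < 1 || t > ncol(kin_series)) {
    stop_bcisim("step index out of range", "bcisim_index_error")
  }
  idx <- pmax(t - 0:n_lags, 1L)
  as.numeric(kin_series[, idx])
}

#' Lagged input matrix for a whole trial
#'
#' Row `t` equals [build_lagged_input()] at step `t`.
#'
#' @inheritParams build_lagged_input
#' @return `T x (channels * (n_lags + 1))` matrix.
#' @export
lagged_input_matrix <- function(kin_series, n_lags = 4) {
  Tn <- ncol(kin_series)
  nc <- nrow(kin_series)
  out <- matrix(0, Tn, nc * (n_lags + 1))
  for (l in 0:n_lags) {
    idx <- pmax(seq_len(Tn) - l, 1L)
    out[, (l * nc + 1):((l + 1) * nc)] <- t(kin_series[, idx, drop = FALSE])
  }
  out
}

xavier <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialize an emulator network
#'
#' The shared encoder is initialized once; one readout module is created per
#' session, sized to that session's neuron count. All draws are governed by
#' `seed`.
#'
#' @param config An [emulator_config()].
#' @param session_neurons Named integer vector: neuron count per session id.
#' @param seed Integer seed.
#' @return Object of class `emulator_net`.
#' @export
init_emulator <- function(config = emulator_config(), session_neurons,
                          seed = 1L) {
  stopifnot(length(session_neurons) >= 1, !is.null(names(session_neurons)))
  set.seed(seed)
  w <- config$encoder_widths
  d <- config$input_dim
  encoder <- list(
    W1 = xavier(d, w[1]), b1 = numeric(w[1]),
    W2 = xavier(w[1], w[2]), b2 = numeric(w[2]),
    W3 = xavier(w[2], w[3]), b3 = numeric(w[3])
  )
  readouts <- lapply(session_neurons, function(C) {
    list(Wh = xavier(w[3], config$readout_hidden_width),
         bh = numeric(config$readout_hidden_width),
         Wo = xavier(config$readout_hidden_width, C),
         bo = numeric(C))
  })
  structure(
    list(config = config, encoder = encoder, readouts = readouts,
         active_session = names(session_neurons)[1], seed = as.integer(seed),
         train_log = NULL),
    class = "emulator_net"
  )
}

#' @export
print.emulator_net <- function(x, ...) {
  cat(sprintf("<emulator_net: %d->%s->%d latent, %d session readout(s), active '%s'>\n",
              x$config$input_dim,
              paste(x$config$encoder_widths[-length(x$config$encoder_widths)],
                    collapse = "->"),
              x$config$encoder_widths[length(x$config$encoder_widths)],
              length(x$readouts), x$active_session))
  invisible(x)
}

#' Set the active session readout
#' @param net An `emulator_net`.
#' @param session_id Session whose readout module to activate.
#' @return The network with `active_session` set.
#' @export
set_active_session <- function(net, session_id) {
  if (!session_id %in% names(net$readouts)) {
    stop_bcisim(sprintf("no readout module for session '%s'", session_id),
                "bcisim_missing_readout")
  }
  net$active_session <- session_id
  net
}

addb <- function(Z, b) Z + rep(b, each = nrow(Z))

# Full forward pass keeping intermediate activations (for backprop).
emu_forward_full <- function(net, X) {
  e <- net$encoder
  r <- net$readouts[[net$active_session]]
  H1 <- tanh(addb(X %*% e$W1, e$b1))
  H2 <- tanh(addb(H1 %*% e$W2, e$b2))
  H3 <- tanh(addb(H2 %*% e$W3, e$b3))
  H4 <- tanh(addb(H3 %*% r$Wh, r$bh))
  Zo <- addb(H4 %*% r$Wo, r$bo)
  list(H1 = H1, H2 = H2, H3 = H3, H4 = H4, Zo = Zo, out = pmax(Zo, 0))
}

#' Forward pass of the emulator
#'
#' `ReLU(readout(tanh-encoder(x)))`; output entries are non-negative firing
#' rates (spikes/s) for the active session's neurons.
#'
#' @param net An `emulator_net` with `active_session` set.
#' @param x A 95-vector (one lagged input) or an `N x 95` matrix.
#' @return A rates vector of length `C_s`, or an `N x C_s` matrix.
#' @export
forward <- function(net, x) {
  if (is.null(net$readouts[[net$active_session]])) {
    stop_bcisim("active session has no readout module",
                "bcisim_missing_readout")
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1) else x
  out <- emu_forward_full(net, X)$out
  if (vec) as.numeric(out) else out
}

#' Mean absolute error between rate arrays
#' @param predicted,target Equal-shaped numeric arrays (spikes/s).
#' @return Scalar mean of `|predicted - target|` over all entries.
#' @export
mae_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target)) {
    stop_bcisim("shape mismatch between predicted and target rates",
                "bcisim_shape_mismatch")
  }
  mean(abs(predicted - target))
}

# MAE gradient wrt all trainable weights (encoder + active readout).
emu_backward <- function(net, X, Y, fw = NULL) {
  e <- net$encoder
  r <- net$readouts[[net$active_session]]
  if (is.null(fw)) fw <- emu_forward_full(net, X)
  G <- sign(fw$out - Y) / length(Y)
  G <- G * (fw$Zo > 0)
  gWo <- crossprod(fw$H4, G); gbo <- colSums(G)
  D4 <- tcrossprod(G, r$Wo) * (1 - fw$H4^2)
  gWh <- crossprod(fw$H3, D4); gbh <- colSums(D4)
  D3 <- tcrossprod(D4, r$Wh) * (1 - fw$H3^2)
  gW3 <- crossprod(fw$H2, D3); gb3 <- colSums(D3)
  D2 <- tcrossprod(D3, e$W3) * (1 - fw$H2^2)
  gW2 <- crossprod(fw$H1, D2); gb2 <- colSums(D2)
  D1 <- tcrossprod(D2, e$W2) * (1 - fw$H1^2)
  gW1 <- crossprod(X, D1); gb1 <- colSums(D1)
  list(encoder = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                      W3 = gW3, b3 = gb3),
       readout = list(Wh = gWh, bh = gbh, Wo = gWo, bo = gbo))
}

grad_inf_norm <- function(g) {
  max(vapply(c(g$encoder, g$readout), function(m) max(abs(m)), numeric(1)))
}

#' Training control parameters
#'
#' @param batch_size Minibatch size for the adaptive first-order optimizer.
#' @param lr Adam learning rate.
#' @param steps_per_visit Optimizer iteration budget per session visit;
#'   `NULL` uses the contract cap of `200 x n_trials`.
#' @param grad_tol Infinity-norm gradient threshold terminating a visit.
#' @param max_rounds Cap on training rounds.
#' @param convergence_window,convergence_frac Stop when the variance of the
#'   last `convergence_window` round errors drops below `convergence_frac`
#'   times their mean.
#' @param warm_start_bias Initialize each readout's output bias to the
#'   session's mean rates on first training encounter.
#' @param lr_decay Multiplicative learning-rate decay applied per round by
#'   [train_schedule()] (default 0.85).
#' @param tail_average Fraction of each visit's final iterations whose
#'   weights are averaged into the returned weights (default 0, keeping the
#'   last iterate; averaging is used by the readout polish stage, where the
#'   learning rate is small).
#' @param polish_steps Optimizer iterations of the post-schedule readout
#'   polish: with the shared encoder frozen at the best round, each
#'   session's readout module is refined on cached encoder outputs at
#'   `polish_lr`, with tail averaging over the final 30% of iterations to
#'   shrink the stochastic-gradient noise ball (which an L1 loss converts
#'   directly into extra MAE). Set 0 to disable.
#' @param polish_lr Learning rate of the polish stage.
#' @return List of class `emulator_control`.
#' @export
emulator_control <- function(batch_size = 1024, lr = 5e-3,
                             steps_per_visit = NULL, grad_tol = 1e-6,
                             max_rounds = 40, convergence_window = 100,
                             convergence_frac = 0.05,
                             warm_start_bias = TRUE, lr_decay = 0.85,
                             tail_average = 0, polish_steps = 1500,
                             polish_lr = 1e-3) {
  structure(list(batch_size = batch_size, lr = lr,
                 steps_per_visit = steps_per_visit, grad_tol = grad_tol,
                 max_rounds = max_rounds,
                 convergence_window = convergence_window,
                 convergence_frac = convergence_frac,
                 warm_start_bias = warm_start_bias, lr_decay = lr_decay,
                 tail_average = tail_average, polish_steps = polish_steps,
                 polish_lr = polish_lr),
            class = "emulator_control")
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * grads[[nm]]
    st$v <- b2 * st$v + (1 - b2) * grads[[nm]]^2
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the emulator on one session's examples
#'
#' Minimizes the MAE between emulated and target firing rates over the
#' (lagged input, rate) examples of the active session using a minibatch
#' adaptive first-order optimizer (Adam). A visit terminates when the
#' full-batch loss-gradient infinity norm falls below `grad_tol` (checked
#' exactly at entry and via the epoch-accumulated gradient thereafter) or
#' when the iteration budget (`steps_per_visit`, capped at `200 x n_trials`)
#' is exhausted. Only the shared encoder and the active session's readout
#' module are modified.
#'
#' @param net An `emulator_net` with the target session active.
#' @param X `N x input_dim` matrix of lagged inputs.
#' @param Y `N x C_s` matrix of target rates.
#' @param n_trials Number of trials the examples came from (sets the
#'   iteration cap).
#' @param control An [emulator_control()].
#' @return List with `net` (updated), `iterations` used, and final `mae`.
#' @export
train_session <- function(net, X, Y, n_trials,
                          control = emulator_control()) {
  if (nrow(X) == 0) stop_bcisim("empty session", "bcisim_invalid_parameter")
  sid <- net$active_session
  r <- net$readouts[[sid]]
  if (isTRUE(control$warm_start_bias) && !isTRUE(r$initialized)) {
    # first encounter: start the rectified-linear output layer at the right
    # operating point -- bias at the neuron's mean rate and output weights
    # scaled to the neuron's rate SD, so the optimizer refines shape rather
    # than spending iterations growing weight magnitudes
    r$bo <- colMeans(Y)
    sds <- apply(Y, 2, sd)
    r$Wo <- sweep(r$Wo, 2, pmax(sds, 1e-3), `*`)
    r$initialized <- TRUE
    net$readouts[[sid]] <- r
  }

  # exact full-batch entry check
  fw <- emu_forward_full(net, X)
  g <- emu_backward(net, X, Y, fw)
  if (grad_inf_norm(g) < control$grad_tol) {
    return(list(net = net, iterations = 0L, mae = mae_loss(fw$out, Y)))
  }

  cap <- 200L * n_trials
  budget <- min(cap, control$steps_per_visit %||% cap)
  params <- c(net$encoder, stats::setNames(
    net$readouts[[sid]][c("Wh", "bh", "Wo", "bo")],
    c("Wh", "bh", "Wo", "bo")))
  astate <- adam_init(params)
  N <- nrow(X)
  bs <- min(control$batch_size, N)
  iter <- 0L
  t_adam <- 0L
  tail_frac <- control$tail_average %||% 0
  tail_start <- if (tail_frac > 0) budget - ceiling(tail_frac * budget) + 1L
                else budget + 1L
  avg <- NULL
  n_avg <- 0L
  repeat {
    ord <- sample.int(N)
    acc <- NULL
    for (start in seq(1, N, by = bs)) {
      if (iter >= budget) break
      idx <- ord[start:min(start + bs - 1, N)]
      net$encoder <- params[c("W1", "b1", "W2", "b2", "W3", "b3")]
      net$readouts[[sid]][c("Wh", "bh", "Wo", "bo")] <-
        params[c("Wh", "bh", "Wo", "bo")]
      g <- emu_backward(net, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      gl <- c(g$encoder, g$readout)
      # epoch-accumulated gradient (example-weighted) for the stop check
      wt <- length(idx) / N
      acc <- if (is.null(acc)) lapply(gl, `*`, wt)
             else purrr::map2(acc, gl, function(a, b) a + b * wt)
      t_adam <- t_adam + 1L
      upd <- adam_step(params, gl, astate, control$lr, t_adam)
      params <- upd$params
      astate <- upd$state
      iter <- iter + 1L
      if (iter >= tail_start) {
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) params
               else purrr::map2(avg, params, function(a, p) {
                 a + (p - a) / n_avg
               })
      }
    }
    if (!is.null(acc) && max(vapply(acc, function(m) max(abs(m)),
                                    numeric(1))) < control$grad_tol) break
    if (iter >= budget) break
  }
  if (!is.null(avg) && n_avg > 1L) params <- avg
  net$encoder <- params[c("W1", "b1", "W2", "b2", "W3", "b3")]
  net$readouts[[sid]][c("Wh", "bh", "Wo", "bo")] <-
    params[c("Wh", "bh", "Wo", "bo")]
  mae <- mae_loss(emu_forward_full(net, X)$out, Y)
  list(net = net, iterations = iter, mae = mae)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Encoder output (50-d latent) for a batch of lagged inputs.
encode_latent <- function(net, X) {
  e <- net$encoder
  H1 <- tanh(addb(X %*% e$W1, e$b1))
  H2 <- tanh(addb(H1 %*% e$W2, e$b2))
  tanh(addb(H2 %*% e$W3, e$b3))
}

# Post-schedule refinement of one session's readout module with the shared
# encoder frozen: the encoder output is computed once and the two readout
# layers are optimized on the cached latents. Tail averaging over the final
# 30% of iterations returns an averaged iterate rather than the last one.
polish_readout <- function(net, sid, X, Y, control) {
  H3 <- encode_latent(net, X)
  r <- net$readouts[[sid]]
  params <- r[c("Wh", "bh", "Wo", "bo")]
  astate <- adam_init(params)
  N <- nrow(H3)
  bs <- min(control$batch_size, N)
  budget <- control$polish_steps
  tail_start <- budget - ceiling(0.3 * budget) + 1L
  avg <- NULL; n_avg <- 0L
  iter <- 0L
  fwd <- function(p, H) {
    H4 <- tanh(addb(H %*% p$Wh, p$bh))
    list(H4 = H4, Zo = addb(H4 %*% p$Wo, p$bo))
  }
  repeat {
    ord <- sample.int(N)
    for (start in seq(1, N, by = bs)) {
      if (iter >= budget) break
      idx <- ord[start:min(start + bs - 1, N)]
      H <- H3[idx, , drop = FALSE]
      f <- fwd(params, H)
      G <- sign(pmax(f$Zo, 0) - Y[idx, , drop = FALSE]) / length(idx) /
        ncol(Y)
      G <- G * (f$Zo > 0)
      D4 <- tcrossprod(G, params$Wo) * (1 - f$H4^2)
      gl <- list(Wh = crossprod(H, D4), bh = colSums(D4),
                 Wo = crossprod(f$H4, G), bo = colSums(G))
      if (max(vapply(gl, function(m) max(abs(m)), numeric(1))) <
            control$grad_tol) {
        iter <- budget
        break
      }
      iter <- iter + 1L
      upd <- adam_step(params, gl, astate, control$polish_lr, iter)
      params <- upd$params
      astate <- upd$state
      if (iter >= tail_start) {
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) params
               else purrr::map2(avg, params, function(a, p) a + (p - a) / n_avg)
      }
    }
    if (iter >= budget) break
  }
  if (!is.null(avg) && n_avg > 1L) params <- avg
  # keep the polish only when it improves the session's training MAE
  old_mae <- mae_loss(pmax(addb(tanh(addb(H3 %*% r$Wh, r$bh)) %*% r$Wo,
                                r$bo), 0), Y)
  f <- fwd(params, H3)
  new_mae <- mae_loss(pmax(f$Zo, 0), Y)
  if (new_mae < old_mae) {
    net$readouts[[sid]][c("Wh", "bh", "Wo", "bo")] <- params
    attr(net$readouts[[sid]], "polish_mae") <- new_mae
  }
  net
}

#' Assemble paired training examples from kinematic and neural trials
#'
#' Pairs each kinematic dataset with each neural session via the PCA /
#' Hungarian procedure, resamples kinematic trials to the neural time grid
#' and precomputes lagged inputs.
#'
#' @param kin_list Named list of `kinematic_trials` tibbles (one per subject).
#' @param sessions Named list of `neural_trials` tibbles (one per session).
#' @return Tibble of class `paired_dataset`: one row per (subject, session,
#'   trial pair), with list-columns `X` (lagged inputs, `T x 95`) and `Y`
#'   (target rates, `T x C_s`).
#' @export
make_paired_dataset <- function(kin_list, sessions) {
  stopifnot(length(kin_list) >= 1, length(sessions) >= 1)
  if (is.null(names(sessions))) {
    names(sessions) <- vapply(sessions, function(s) s$session_id[1],
                              character(1))
  }
  if (is.null(names(kin_list))) {
    names(kin_list) <- vapply(kin_list, function(k) k$subject_id[1],
                              character(1))
  }
  kin_embs <- lapply(kin_list, function(k) {
    project_pca2(build_trial_matrix(k), condition = k$condition,
                 trial_id = k$trial_id)
  })
  out <- purrr::imap(sessions, function(ses, sid) {
    n_steps <- ncol(ses$rates[[1]])
    ne <- project_pca2(build_trial_matrix(ses), condition = ses$condition,
                       trial_id = ses$trial_id)
    pairs <- replicate_pairings(kin_embs, ne)
    purrr::pmap(pairs, function(condition, kin_trial_id, neu_trial_id, cost,
                                subject) {
      kin <- kin_list[[subject]]
      km <- kin$sensors[[match(kin_trial_id, kin$trial_id)]]
      km <- resample_trial(km, n_steps)
      rates <- ses$rates[[match(neu_trial_id, ses$trial_id)]]
      tibble(session_id = sid, subject = subject, condition = condition,
             kin_trial_id = kin_trial_id, neu_trial_id = neu_trial_id,
             X = list(lagged_input_matrix(km)), Y = list(t(rates)))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("paired_dataset", class(out))
  out
}

#' Split paired trials into training and validation sets
#'
#' Random split stratified by (session, condition): within each stratum
#' `round(fraction * n)` pairs train and the rest validate, so the realized
#' per-condition ratio is within one trial of the requested one.
#'
#' @param pairs A `paired_dataset` (or any tibble with `condition`, and
#'   optionally `session_id`, columns).
#' @param fraction Training fraction in (0, 1); default 0.85.
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
split_train_validation <- function(pairs, fraction = 0.85, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_bcisim("`fraction` must lie strictly between 0 and 1",
                "bcisim_invalid_parameter")
  }
  if (nrow(pairs) < 2) {
    stop_bcisim("need at least 2 pairs to split", "bcisim_invalid_parameter")
  }
  set.seed(seed)
  strata <- if ("session_id" %in% names(pairs)) {
    interaction(pairs$session_id, pairs$condition, drop = TRUE)
  } else factor(pairs$condition)
  train_idx <- unlist(lapply(split(seq_len(nrow(pairs)), strata),
                             function(idx) {
    n_tr <- round(fraction * length(idx))
    n_tr <- max(min(n_tr, length(idx) - 1L), 1L)
    sample(idx, n_tr)
  }))
  train_idx <- sort(train_idx)
  list(train = pairs[train_idx, ],
       validation = pairs[-train_idx, ])
}

#' Stack one session's paired examples into training matrices
#'
#' @param pairs A `paired_dataset`.
#' @param sid Session id to extract.
#' @return List with `X` (all lagged inputs, row-bound), `Y` (all target
#'   rates) and `n_trials` (number of pairs stacked).
#' @export
stack_session_examples <- function(pairs, sid) {
  sub <- pairs[pairs$session_id == sid, ]
  list(X = do.call(rbind, sub$X), Y = do.call(rbind, sub$Y),
       n_trials = nrow(sub))
}

#' Run the round-based transfer training schedule
#'
#' One round visits every session once in seeded random order (without
#' replacement), training the shared encoder plus that session's readout via
#' [train_session()]. The round error is the mean across-session MAE. Training
#' stops when the variance of the last `convergence_window` round errors falls
#' below `convergence_frac` of their mean, or at `max_rounds`. The returned
#' network is the snapshot from the minimum-error round.
#'
#' @param net An initialized `emulator_net`.
#' @param pairs A `paired_dataset` (training split).
#' @param seed Integer seed (schedule order and minibatch shuffles).
#' @param control An [emulator_control()].
#' @return The trained `emulator_net`; `$train_log` holds a tibble of round
#'   errors and `$best_round` the selected round.
#' @export
train_schedule <- function(net, pairs, seed = 1L,
                           control = emulator_control()) {
  sids <- intersect(names(net$readouts), unique(pairs$session_id))
  if (length(sids) < 1) {
    stop_bcisim("no sessions shared between network and pairs",
                "bcisim_invalid_parameter")
  }
  data_by_session <- lapply(stats::setNames(sids, sids),
                            function(s) stack_session_examples(pairs, s))
  set.seed(seed)
  round_errors <- numeric(0)
  iter_counts <- stats::setNames(integer(length(sids)), sids)
  best <- list(error = Inf, net = NULL, round = NA_integer_)
  for (round_i in seq_len(control$max_rounds)) {
    round_control <- control
    round_control$lr <- control$lr * (control$lr_decay %||% 1)^(round_i - 1)
    order_s <- sample(sids)
    errs <- numeric(length(order_s))
    for (j in seq_along(order_s)) {
      s <- order_s[j]
      net <- set_active_session(net, s)
      d <- data_by_session[[s]]
      res <- train_session(net, d$X, d$Y, d$n_trials, round_control)
      net <- res$net
      iter_counts[s] <- iter_counts[s] + res$iterations
      errs[j] <- res$mae
    }
    round_errors[round_i] <- mean(errs)
    if (round_errors[round_i] < best$error) {
      best <- list(error = round_errors[round_i],
                   net = net[c("encoder", "readouts")], round = round_i)
    }
    w <- control$convergence_window
    if (round_i >= w) {
      recent <- round_errors[(round_i - w + 1):round_i]
      if (var(recent) < control$convergence_frac * mean(recent)) break
    }
  }
  net$encoder <- best$net$encoder
  net$readouts <- best$net$readouts
  if ((control$polish_steps %||% 0) > 0) {
    for (s in sids) {
      d <- data_by_session[[s]]
      net <- polish_readout(net, s, d$X, d$Y, control)
    }
  }
  net$train_log <- tibble(round = seq_along(round_errors),
                          mae = round_errors)
  net$best_round <- best$round
  net$iterations <- iter_counts
  net
}

#' Train a full emulator from a paired dataset
#'
#' Convenience wrapper: initializes the network (one readout per session in
#' `pairs`) and runs [train_schedule()].
#'
#' @inheritParams train_schedule
#' @param config An [emulator_config()].
#' @param withhold_condition Optionally, a condition (1-8) whose pairs are
#'   excluded from training, producing a reduced emulator for
#'   generalization testing.
#' @return Trained `emulator_net`.
#' @export
train_emulator <- function(pairs, config = emulator_config(), seed = 1L,
                           control = emulator_control(),
                           withhold_condition = NULL) {
  if (!is.null(withhold_condition)) {
    if (!withhold_condition %in% pairs$condition) {
      stop_bcisim("withheld condition not present in the paired data",
                  "bcisim_invalid_parameter")
    }
    pairs <- pairs[pairs$condition != withhold_condition, ]
  }
  counts <- vapply(split(pairs$Y, pairs$session_id),
                   function(ys) ncol(ys[[1]]), integer(1))
  net <- init_emulator(config, counts, seed = seed)
  net <- train_schedule(net, pairs, seed = seed, control = control)
  net$withheld_condition <- withhold_condition
  net
}

#' Emulate a neural trial from a kinematic trial
#'
#' Applies the lag buffer and forward pass at every step of a 25 ms-grid
#' kinematic trial, producing the active session's firing rates.
#'
#' @param net A trained `emulator_net` with `active_session` set.
#' @param kin Channels-by-time kinematic matrix on the 25 ms grid (use
#'   [resample_trial()] first otherwise).
#' @return `C_s x T` matrix of non-negative firing rates (spikes/s).
#' @export
emulate_trial <- function(net, kin) {
  X <- lagged_input_matrix(kin, net$config$n_lags)
  t(forward(net, X))
}

#' Per-neuron mean-rate baseline MAE
#'
#' The MAE achieved by predicting, for every timepoint, each neuron's mean
#' training rate; the reference against which emulator efficacy is judged.
#'
#' @param Y_train,Y_test `N x C` rate matrices.
#' @return Scalar MAE of the mean predictor on `Y_test`.
#' @export
baseline_mae <- function(Y_train, Y_test) {
  mu <- colMeans(Y_train)
  mean(abs(sweep(Y_test, 2, mu)))
}

#' @method glance emulator_net
#' @export
glance.emulator_net <- function(x, ...) {
  tibble(
    n_sessions = length(x$readouts),
    input_dim = x$config$input_dim,
    latent_dim = x$config$encoder_widths[length(x$config$encoder_widths)],
    rounds = if (is.null(x$train_log)) 0L else nrow(x$train_log),
    best_round = x$best_round %||% NA_integer_,
    best_mae = if (is.null(x$train_log)) NA_real_ else min(x$train_log$mae)
  )
}

#' @method tidy emulator_net
#' @export
tidy.emulator_net <- function(x, ...) {
  if (is.null(x$train_log)) return(tibble(round = integer(), mae = numeric()))
  x$train_log
}
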