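#' Construct a velocity Kalman filter model
#'
#' State layout is `[V_x, V_y, 1]` (cursor velocity in cm/s plus a constant
#' offset element that absorbs baseline firing). The measurement model maps
#' state to the C observed firing rates, `z_k = H x_k + q_k`, and the state
#' model is `x_k = A x_{k-1} + w_k`.
#'
#' @param A State-transition matrix (d x d, offset row `[0, 0, 1]`).
#' @param W State-noise covariance (symmetric PSD, zero offset row/col).
#' @param H Measurement matrix (C x d).
#' @param Q Measurement-noise covariance (C x C, symmetric PSD).
#' @param dt Tick period in seconds (default 0.025).
#' @return Object of class `kalman_model` (gain not yet computed; see
#'   [steady_state_gain()]).
#' @export
kalman_model <- function(A, W, H, Q, dt = 0.025) {
  d <- nrow(A)
  stopifnot(ncol(A) == d, identical(dim(W), dim(A)), ncol(H) == d,
            nrow(Q) == nrow(H), ncol(Q) == nrow(H))
  if (max(abs(W - t(W))) > 1e-8 || max(abs(Q - t(Q))) > 1e-8) {
    stop_bcisim("W and Q must be symmetric", "bcisim_invalid_parameter")
  }
  structure(list(A = A, W = W, H = H, Q = Q, dt = dt, d = d,
                 C = nrow(H), K = NULL, P = NULL),
            class = "kalman_model")
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model: %d-dim state, %d neurons, gain %s>\n",
              x$d, x$C, if (is.null(x$K)) "not computed" else "steady-state"))
  invisible(x)
}

#' Fit the state-transition model from reference velocities
#'
#' Least squares of `x_k` on `x_{k-1}` over consecutive reference-velocity
#' samples, with the offset row fixed at `[0, 0, 1]`. `W` is the residual
#' covariance with zero offset row/column.
#'
#' @param vel `N x 2` matrix of consecutive reference velocities (cm/s), or a
#'   list of such matrices (e.g. one per calibration trial; transitions
#'   across list elements are not used as consecutive pairs).
#' @return List with `A` (3 x 3) and `W` (3 x 3).
#' @export
fit_state_model <- function(vel) {
  if (is.matrix(vel)) vel <- list(vel)
  prev <- do.call(rbind, lapply(vel, function(v) v[-nrow(v), , drop = FALSE]))
  nxt <- do.call(rbind, lapply(vel, function(v) v[-1, , drop = FALSE]))
  if (is.null(prev) || nrow(prev) < 1) {
    stop_bcisim("need at least 2 consecutive velocity samples",
                "bcisim_invalid_parameter")
  }
  X <- cbind(prev, 1)            # x_{k-1} rows: [vx, vy, 1]
  fit <- stats::lm.fit(X, nxt)   # nxt ~ X
  A_top <- t(fit$coefficients)   # 2 x 3
  A_top[is.na(A_top)] <- 0       # aliased directions (e.g. constant input)
  A <- rbind(A_top, c(0, 0, 1))
  dimnames(A) <- NULL
  res <- as.matrix(fit$residuals)
  W2 <- if (nrow(res) > 1) stats::cov(res) else matrix(0, 2, 2)
  W <- matrix(0, 3, 3)
  W[1:2, 1:2] <- (W2 + t(W2)) / 2
  list(A = A, W = W)
}

#' Fit the measurement model by ordinary least squares
#'
#' `H = argmin ||z - H x||^2` (one OLS row per neuron) and `Q` the empirical
#' covariance of the residuals `z - H x`.
#'
#' @param z `C x N` matrix of firing rates.
#' @param x `d x N` matrix of reference states (`[vx; vy; 1]` columns).
#' @return List with `H` (C x d) and `Q` (C x C).
#' @export
fit_measurement_model <- function(z, x) {
  d <- nrow(x); N <- ncol(x)
  if (N <= d) {
    stop_bcisim("need more samples than state dimensions",
                "bcisim_invalid_parameter")
  }
  if (qr(t(x))$rank < d) {
    stop_bcisim("reference states are rank-deficient; velocities do not span the state space",
                "bcisim_rank_error")
  }
  fit <- stats::lm.fit(t(x), t(z))
  H <- t(as.matrix(fit$coefficients))
  res <- t(as.matrix(fit$residuals))        # C x N
  Q <- tcrossprod(res) / (N - 1)
  Q <- (Q + t(Q)) / 2
  list(H = H, Q = Q)
}

#' Steady-state Kalman gain via the discrete Riccati recursion
#'
#' Iterates the prediction/update covariance recursion until the prior
#' covariance changes by less than `tol` in the infinity norm, then returns
#' the steady-state gain `K = P- H' (H P- H' + Q)^{-1}` and the fixed-point
#' covariances. `Q` is regularized by `1e-8 * mean(diag(Q)) * I` before
#' inversion to guard near-singular residual covariances.
#'
#' @param model A [kalman_model()].
#' @param tol Convergence tolerance on the prior covariance (default 1e-10).
#' @param max_iter Iteration cap (default 1e5).
#' @return The model with `K` (steady-state gain, d x C), `P` (posterior
#'   covariance) and `P_prior` filled in.
#' @export
steady_state_gain <- function(model, tol = 1e-10, max_iter = 1e5) {
  A <- model$A; W <- model$W; H <- model$H
  Q <- model$Q
  reg <- 1e-8 * mean(diag(Q))
  if (!is.finite(reg) || reg <= 0) reg <- 1e-12
  Qr <- Q + diag(reg, nrow(Q))
  d <- model$d
  P <- diag(1, d)
  P[d, ] <- 0; P[, d] <- 0   # offset element is noiseless
  Pm_old <- matrix(Inf, d, d)
  for (i in seq_len(max_iter)) {
    Pm <- A %*% P %*% t(A) + W
    Pm <- (Pm + t(Pm)) / 2
    if (max(abs(Pm - Pm_old)) < tol) {
      S <- H %*% Pm %*% t(H) + Qr
      K <- t(solve(S, H %*% Pm))       # Pm H' S^{-1}
      model$K <- K
      model$P_prior <- Pm
      model$P <- (diag(d) - K %*% H) %*% Pm
      return(model)
    }
    Pm_old <- Pm
    S <- H %*% Pm %*% t(H) + Qr
    K <- t(solve(S, H %*% Pm))
    P <- (diag(d) - K %*% H) %*% Pm
    P <- (P + t(P)) / 2
  }
  stop_bcisim("Riccati recursion did not converge within the iteration cap",
              "bcisim_convergence_error")
}

#' Initialize a decoder state
#'
#' @param model A [kalman_model()] with the steady-state gain computed.
#' @param position Initial cursor position (cm), default the workspace center.
#' @return Object of class `decoder_state` with `x = [0, 0, 1]`.
#' @export
decoder_state <- function(model, position = c(0, 0)) {
  if (is.null(model$K)) {
    stop_bcisim("compute the steady-state gain first", "bcisim_invalid_parameter")
  }
  structure(list(x = c(numeric(model$d - 1), 1), position = position),
            class = "decoder_state")
}

#' One steady-state Kalman decode step
#'
#' `x_k = A x_{k-1} + K (z_k - H A x_{k-1})`; the cursor position integrates
#' the decoded velocity over one tick and the offset element is pinned at 1.
#'
#' @param state A [decoder_state()].
#' @param model The [kalman_model()] (gain computed).
#' @param z_k Firing-rate observation (length C, spikes/s).
#' @return Updated `decoder_state`.
#' @export
decode_step <- function(state, model, z_k) {
  if (length(z_k) != model$C) {
    stop_bcisim("observation length does not match the measurement model",
                "bcisim_shape_mismatch")
  }
  xp <- as.numeric(model$A %*% state$x)
  innov <- z_k - as.numeric(model$H %*% xp)
  x <- xp + as.numeric(model$K %*% innov)
  x[model$d] <- 1
  state$x <- x
  state$position <- state$position + x[1:2] * model$dt
  state
}

#' @method tidy kalman_model
#' @export
tidy.kalman_model <- function(x, ...) {
  tibble(
    matrix = c("A", "W", "H", "Q", if (!is.null(x$K)) "K"),
    rows = c(nrow(x$A), nrow(x$W), nrow(x$H), nrow(x$Q),
             if (!is.null(x$K)) nrow(x$K)),
    cols = c(ncol(x$A), ncol(x$W), ncol(x$H), ncol(x$Q),
             if (!is.null(x$K)) ncol(x$K)),
    frobenius = vapply(
      x[c("A", "W", "H", "Q", if (!is.null(x$K)) "K")],
      function(m) sqrt(sum(m^2)), numeric(1))
  )
}

#' @method glance kalman_model
#' @export
glance.kalman_model <- function(x, ...) {
  tibble(state_dim = x$d, n_neurons = x$C,
         gain_computed = !is.null(x$K),
         riccati_residual = if (is.null(x$K)) NA_real_ else {
           Pm <- x$A %*% x$P %*% t(x$A) + x$W
           max(abs(Pm - x$P_prior))
         })
}
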