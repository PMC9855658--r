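# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_bcisim <- function(msg, class, call. = FALSE) {
  cnd <- structure(
    class = c(class, "bcisim_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, class = "bcisim_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper || (integer && x != round(x))) {
    stop_bcisim(
      sprintf("`%s` must be a %s in [%s, %s], got %s",
              name, if (integer) "whole number" else "number",
              format(lower), format(upper),
              paste(format(x), collapse = ",")),
      class
    )
  }
  invisible(x)
}

# Minimum-jerk scalar profile s(tau) on tau in [0, 1]: 10t^3 - 15t^4 + 6t^5.
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

# d s / d tau of the minimum-jerk profile.
min_jerk_deriv <- function(tau) {
  inside <- tau >= 0 & tau <= 1
  out <- numeric(length(tau))
  out[inside] <- 30 * tau[inside]^2 - 60 * tau[inside]^3 + 30 * tau[inside]^4
  out
}

# Upper-triangle vector of a square matrix (excluding diagonal).
upper_tri_vec <- function(m) m[upper.tri(m)]

# Pairwise Euclidean distance matrix between rows of two matrices.
cross_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Softplus, numerically stable.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Column-order trial layout: channels concatenated time-major
# (channel 1 all timepoints, then channel 2, ...). `mat` is channels x time.
flatten_trial <- function(mat) as.numeric(t(mat))

unflatten_trial <- function(v, n_channels) {
  matrix(v, nrow = n_channels, byrow = TRUE)
}
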