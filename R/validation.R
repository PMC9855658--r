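#' Peri-event firing-rate averages
#'
#' Trial-averaged rate traces per (neuron, condition), plus the summary trace:
#' the standard deviation, at each timepoint, across all neuron-condition
#' mean traces. Traces are aligned to the go cue (the session window starts
#' 200 ms before it).
#'
#' @param trials A `neural_trials` tibble.
#' @return List with `means` (tibble: neuron, condition, t, rate) and
#'   `sd_trace` (tibble: t, sd). Conditions with no trials are excluded with
#'   a warning.
#' @export
perievent_average <- function(trials) {
  conds <- sort(unique(trials$condition))
  time <- attr(trials, "time")
  if (is.null(time)) time <- seq_len(ncol(trials$rates[[1]]))
  avg <- lapply(conds, function(cc) {
    mats <- trials$rates[trials$condition == cc]
    if (length(mats) == 0) return(NULL)
    Reduce(`+`, mats) / length(mats)
  })
  keep <- !vapply(avg, is.null, logical(1))
  if (!all(keep)) warning("conditions with no trials were excluded")
  avg <- avg[keep]
  conds <- conds[keep]
  means <- purrr::map2_dfr(avg, conds, function(m, cc) {
    tibble(neuron = rep(seq_len(nrow(m)), times = ncol(m)),
           condition = cc,
           t = rep(time, each = nrow(m)),
           rate = as.numeric(m))
  })
  stacked <- do.call(rbind, avg)      # (neuron x condition) rows, time cols
  sd_trace <- tibble(t = time, sd = apply(stacked, 2, sd))
  list(means = means, sd_trace = sd_trace)
}

#' Cluster geometry of a 2D trial embedding
#'
#' Per-condition cluster centers, mean intra-cluster spread (mean distance of
#' trials to their center) and the pairwise center-distance matrix.
#'
#' @param emb A `trial_embedding` tibble (columns `condition`, `pc1`, `pc2`).
#' @return List with `centers` (tibble), `spread` (named vector) and
#'   `dist_matrix` (k x k symmetric, zero diagonal).
#' @export
cluster_geometry <- function(emb) {
  centers <- emb |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(pc1 = mean(.data$pc1), pc2 = mean(.data$pc2),
                     .groups = "drop") |>
    dplyr::arrange(.data$condition)
  spread <- vapply(centers$condition, function(cc) {
    pts <- emb[emb$condition == cc, c("pc1", "pc2")]
    ctr <- unlist(centers[centers$condition == cc, c("pc1", "pc2")])
    mean(sqrt((pts$pc1 - ctr[1])^2 + (pts$pc2 - ctr[2])^2))
  }, numeric(1))
  names(spread) <- centers$condition
  cmat <- as.matrix(centers[, c("pc1", "pc2")])
  D <- as.matrix(stats::dist(cmat))
  dimnames(D) <- list(centers$condition, centers$condition)
  list(centers = centers, spread = spread, dist_matrix = D)
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(rep(i, nrow(sub)), sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries.
#' The one-sided p-value is the fraction of row/column label permutations of
#' the second matrix (including the identity) whose permuted correlation is
#' at least the observed one. When `factorial(n) <= n_perm` all permutations
#' are enumerated exactly; otherwise `n_perm - 1` random permutations plus
#' the identity are used.
#'
#' @param D1,D2 Symmetric distance matrices with zero diagonals, same size,
#'   `n >= 4`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the sampled case.
#' @return List with `r` (observed correlation), `p`, `n_perm_used`, and
#'   `exhaustive` flag.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1L) {
  n <- nrow(D1)
  if (!identical(dim(D1), dim(D2)) || n < 4) {
    stop_bcisim("matrices must be equal-sized with n >= 4",
                "bcisim_invalid_parameter")
  }
  if (max(abs(D1 - t(D1))) > 1e-10 || max(abs(D2 - t(D2))) > 1e-10 ||
      any(abs(diag(D1)) > 1e-10) || any(abs(diag(D2)) > 1e-10)) {
    stop_bcisim("inputs must be symmetric with zero diagonals",
                "bcisim_invalid_parameter")
  }
  v1 <- upper_tri_vec(D1)
  r_obs <- cor(v1, upper_tri_vec(D2))
  nf <- factorial(n)
  if (nf <= n_perm) {
    perms <- all_permutations(n)
  } else {
    set.seed(seed)
    perms <- rbind(seq_len(n),
                   t(replicate(n_perm - 1L, sample.int(n))))
  }
  r_perm <- apply(perms, 1, function(p) cor(v1, upper_tri_vec(D2[p, p])))
  list(r = r_obs, p = mean(r_perm >= r_obs - 1e-12),
       n_perm_used = nrow(perms), exhaustive = nf <= n_perm)
}

#' jPCA: rotational modes of trial-averaged population activity
#'
#' Fits skew-symmetric linear dynamics to the top principal components of
#' target-averaged firing rates: (1) average rates per condition, (2)
#' subtract the cross-condition mean trace, (3) project onto the top `n_pc`
#' PCs of the stacked averages, (4) estimate state derivatives by central
#' finite differences on the sample grid, (5) solve
#' `M = argmin_{M = -M'} ||Xdot - X M'||_F` in closed form over the
#' skew-symmetric basis, (6) extract rotation planes from the eigenvector
#' pairs of M ordered by |Im(lambda)|.
#'
#' @param trials A `neural_trials` tibble with >= 2 conditions.
#' @param n_pc Number of principal components (default 6; reduced with a
#'   warning when the averaged data have lower rank).
#' @param dt Sample period, s (default from the trials' time attribute).
#' @return Object of class `jpca_result`: `M` (skew-symmetric, n_pc x n_pc),
#'   `planes` (list of n_pc x 2 orthonormal bases), `freq` (rad/s per plane,
#'   decreasing), `var_captured` (fraction of the n_pc-space variance per
#'   plane), `trajectories` (tibble: condition, t, plane, jpc1, jpc2),
#'   `residual` (skew fit) and `residual_unconstrained`.
#' @export
jpca <- function(trials, n_pc = 6, dt = NULL) {
  conds <- sort(unique(trials$condition))
  if (length(conds) < 2) {
    stop_bcisim("need at least 2 conditions", "bcisim_invalid_parameter")
  }
  time <- attr(trials, "time")
  if (is.null(dt)) dt <- if (!is.null(time)) diff(time[1:2]) else 0.025
  avg <- lapply(conds, function(cc) {
    mats <- trials$rates[trials$condition == cc]
    Reduce(`+`, mats) / length(mats)       # neurons x T
  })
  Tn <- ncol(avg[[1]])
  cross_mean <- Reduce(`+`, avg) / length(avg)
  centered <- lapply(avg, function(m) m - cross_mean)
  X_stack <- do.call(rbind, lapply(centered, t))   # (cond*T) x neurons
  ctr <- colMeans(X_stack)
  Xc <- sweep(X_stack, 2, ctr)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < n_pc) {
    warning(sprintf("data rank %d below requested %d PCs; reduced", rank, n_pc))
    n_pc <- rank
  }
  V <- sv$v[, seq_len(n_pc), drop = FALSE]
  scores <- lapply(centered, function(m) sweep(t(m), 2, ctr) %*% V)  # T x n_pc

  # central differences on interior points
  X_rows <- NULL
  Xdot_rows <- NULL
  for (s in scores) {
    interior <- 2:(Tn - 1)
    X_rows <- rbind(X_rows, s[interior, , drop = FALSE])
    Xdot_rows <- rbind(Xdot_rows,
                       (s[interior + 1, , drop = FALSE] -
                        s[interior - 1, , drop = FALSE]) / (2 * dt))
  }

  # closed-form LS over the skew-symmetric basis: columns of the design are
  # vec(X %*% t(E_k)) for each basis matrix E_k = e_i e_j' - e_j e_i' (i < j)
  pairs_ij <- which(upper.tri(diag(n_pc)), arr.ind = TRUE)
  design <- vapply(seq_len(nrow(pairs_ij)), function(k) {
    i <- pairs_ij[k, 1]; j <- pairs_ij[k, 2]
    # M has m_ij at (i,j) = -a_k, (j,i) = +a_k convention: build from E
    Mk <- matrix(0, n_pc, n_pc)
    Mk[i, j] <- 1; Mk[j, i] <- -1
    as.numeric(X_rows %*% t(Mk))
  }, numeric(nrow(X_rows) * n_pc))
  b <- as.numeric(Xdot_rows)
  coef <- stats::lm.fit(design, b)$coefficients
  M <- matrix(0, n_pc, n_pc)
  for (k in seq_len(nrow(pairs_ij))) {
    i <- pairs_ij[k, 1]; j <- pairs_ij[k, 2]
    M[i, j] <- coef[k]; M[j, i] <- -coef[k]
  }
  residual <- sum((Xdot_rows - X_rows %*% t(M))^2)
  M_unc <- t(stats::lm.fit(X_rows, Xdot_rows)$coefficients)
  residual_unc <- sum((Xdot_rows - X_rows %*% t(M_unc))^2)

  ei <- eigen(M)
  im <- Im(ei$values)
  pos <- which(im > 1e-12)
  pos <- pos[order(im[pos], decreasing = TRUE)]
  planes <- lapply(pos, function(k) {
    v <- ei$vectors[, k]
    basis <- cbind(Re(v), Im(v))
    qr.Q(qr(basis))
  })
  freq <- im[pos]
  total_var <- sum(apply(X_rows, 2, var))
  var_captured <- vapply(planes, function(B) {
    pr <- X_rows %*% B
    sum(apply(pr, 2, var)) / total_var
  }, numeric(1))

  trajectories <- purrr::imap_dfr(planes, function(B, pi) {
    purrr::map2_dfr(scores, conds, function(s, cc) {
      pr <- s %*% B
      tibble(condition = cc, t = if (!is.null(time)) time else
               dt * (seq_len(Tn) - 1), plane = pi,
             jpc1 = pr[, 1], jpc2 = pr[, 2])
    })
  })
  structure(
    list(M = M, planes = planes, freq = freq, var_captured = var_captured,
         trajectories = trajectories, residual = residual,
         residual_unconstrained = residual_unc, n_pc = n_pc,
         pca_basis = V, pca_center = ctr),
    class = "jpca_result"
  )
}

#' @export
print.jpca_result <- function(x, ...) {
  cat(sprintf("<jpca_result: %d PCs, %d plane(s); top plane %.2f rad/s capturing %.1f%% variance>\n",
              x$n_pc, length(x$planes), x$freq[1], 100 * x$var_captured[1]))
  invisible(x)
}

#' @method glance jpca_result
#' @export
glance.jpca_result <- function(x, ...) {
  tibble(n_planes = length(x$planes),
         top_freq_rad_s = x$freq[1],
         top_freq_hz = x$freq[1] / (2 * pi),
         top_plane_var = x$var_captured[1],
         total_plane_var = sum(x$var_captured),
         skew_residual = x$residual)
}

#' @method tidy jpca_result
#' @export
tidy.jpca_result <- function(x, ...) x$trajectories
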