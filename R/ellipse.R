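# Direct least-squares ellipse fitting (conic constrained to 4ac - b^2 = 1)
# and ellipse distance/arc utilities used by the generalization statistics.

#' Fit an ellipse to 2D points by direct least squares
#'
#' Minimizes the algebraic conic residual subject to the ellipse-specific
#' normalization `4ac - b^2 = 1` (the numerically stable partitioned form of
#' the direct method), guaranteeing an ellipse for any non-degenerate input.
#'
#' @param points `n x 2` matrix (or data frame) of coordinates, `n >= 5`,
#'   not collinear.
#' @return Object of class `ellipse_fit`: conic coefficients
#'   `(a, b, c, d, e, f)` with `b^2 - 4ac < 0`, plus geometric `center`,
#'   `axes` (semi-axes, major first) and `angle` (rotation of the major
#'   axis, radians).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5) {
    stop_bcisim("need at least 5 points to fit an ellipse", "bcisim_fit_error")
  }
  x <- pts[, 1]; y <- pts[, 2]
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2) {
    stop_bcisim("points are collinear; ellipse fit is degenerate",
                "bcisim_fit_error")
  }
  # scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(c(sd(x), sd(y)))
  if (sc < .Machine$double.eps) {
    stop_bcisim("degenerate point configuration", "bcisim_fit_error")
  }
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  Mred <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(Mred[3, ] / 2, -Mred[2, ], Mred[1, ] / 2)
  ei <- eigen(M2)
  evec <- Re(ei$vectors)
  cond_ok <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond_ok > 0)
  if (length(k) == 0) {
    stop_bcisim("no ellipse solution for this configuration",
                "bcisim_fit_error")
  }
  a1 <- evec[, k[1]]
  # normalize to 4ac - b^2 = 1
  a1 <- a1 / sqrt(cond_ok[k[1]])
  coef_s <- c(a1, Tm %*% a1)   # (a, b, c, d, e, f) in scaled frame

  # un-scale: x = (X - mx)/sc etc.
  a <- coef_s[1] / sc^2
  b <- coef_s[2] / sc^2
  cc <- coef_s[3] / sc^2
  d <- coef_s[4] / sc - 2 * a * mx - b * my
  e <- coef_s[5] / sc - 2 * cc * my - b * mx
  f <- coef_s[6] + a * mx^2 + b * mx * my + cc * my^2 -
    coef_s[4] * mx / sc - coef_s[5] * my / sc
  coefs <- c(a = a, b = b, c = cc, d = d, e = e, f = f)

  # geometric parameters
  Amat <- matrix(c(a, b / 2, b / 2, cc), 2)
  center <- solve(2 * Amat, -c(d, e))
  val <- a * center[1]^2 + b * center[1] * center[2] + cc * center[2]^2 +
    d * center[1] + e * center[2] + f
  eg <- eigen(Amat, symmetric = TRUE)
  ax2 <- -val / eg$values
  if (any(ax2 <= 0)) {
    stop_bcisim("degenerate conic (not an ellipse)", "bcisim_fit_error")
  }
  axes <- sqrt(ax2)
  ord <- order(axes, decreasing = TRUE)
  axes <- axes[ord]
  major_vec <- eg$vectors[, ord[1]]
  angle <- atan2(major_vec[2], major_vec[1])
  if (angle < 0) angle <- angle + pi
  structure(list(coefficients = coefs, center = center, axes = axes,
                 angle = angle %% pi),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit: center (%.3g, %.3g), semi-axes (%.3g, %.3g), angle %.3g rad>\n",
              x$center[1], x$center[2], x$axes[1], x$axes[2], x$angle))
  invisible(x)
}

# Boundary point at parameter angle theta.
ellipse_point <- function(e, theta) {
  ca <- cos(e$angle); sa <- sin(e$angle)
  px <- e$axes[1] * cos(theta); py <- e$axes[2] * sin(theta)
  c(e$center[1] + ca * px - sa * py,
    e$center[2] + sa * px + ca * py)
}

#' Minimum distance from a point to an ellipse boundary
#'
#' 1D minimization over the boundary parameter angle with multiple starts
#' (tolerance 1e-10), returning the minimum Euclidean distance; points inside
#' the ellipse get their distance to the boundary.
#'
#' @param p Length-2 point.
#' @param e An [fit_ellipse()] result.
#' @param n_starts Number of multistart intervals (default 16).
#' @return List with `distance` (>= 0) and `theta` (arg min boundary
#'   parameter in `[0, 2*pi)`).
#' @export
point_to_ellipse_distance <- function(p, e, n_starts = 16) {
  obj <- function(th) {
    q <- ellipse_point(e, th)
    (q[1] - p[1])^2 + (q[2] - p[2])^2
  }
  grid <- seq(0, 2 * pi, length.out = n_starts + 1)
  best <- list(objective = Inf, minimum = 0)
  for (i in seq_len(n_starts)) {
    o <- optimize(obj, c(grid[i] - 0.2, grid[i + 1] + 0.2), tol = 1e-12)
    if (o$objective < best$objective) best <- o
  }
  list(distance = sqrt(best$objective), theta = best$minimum %% (2 * pi))
}

# TRUE when angle `th` lies on the circular arc from th1 to th2 that excludes
# all angles in `others` (when one such arc exists; otherwise the shorter arc).
angle_on_arc <- function(th, th1, th2, others = numeric(0)) {
  norm <- function(a) a %% (2 * pi)
  th <- norm(th); th1 <- norm(th1); th2 <- norm(th2); others <- norm(others)
  on_ccw_arc <- function(a, from, to) {
    # ccw arc from `from` to `to`
    norm(a - from) <= norm(to - from) + 1e-12
  }
  arc1_has_other <- any(vapply(others, on_ccw_arc, logical(1),
                               from = th1, to = th2))
  arc2_has_other <- any(vapply(others, on_ccw_arc, logical(1),
                               from = th2, to = th1))
  if (arc1_has_other && !arc2_has_other) return(on_ccw_arc(th, th2, th1))
  if (!arc1_has_other && arc2_has_other) return(on_ccw_arc(th, th1, th2))
  # fall back to the shorter arc
  if (norm(th2 - th1) <= norm(th1 - th2)) on_ccw_arc(th, th1, th2)
  else on_ccw_arc(th, th2, th1)
}

#' Generalization statistics for a withheld posture class
#'
#' Quantifies how a reduced (seven-posture) emulator projects a withheld
#' class into the PCA plane defined by the seven training classes:
#' \describe{
#'   \item{dist_to_ellipse_normalized}{distance of the withheld-cluster
#'     center to the ellipse fit to the 7 training centers, divided by the
#'     mean distance of those centers to the ellipse.}
#'   \item{intra_cluster_ratio}{mean distance of withheld trials to their own
#'     center over the mean (across training clusters) of mean
#'     trial-to-center distances.}
#'   \item{neighbor_distance_normalized}{mean distance of the withheld center
#'     to its two ring-adjacent training centers over the mean
#'     nearest-neighbor distance among training centers.}
#'   \item{projects_between_neighbors}{whether the withheld center's nearest
#'     boundary point falls on the ellipse arc between its two neighbors'
#'     own boundary projections (the arc free of the other training
#'     classes).}
#' }
#'
#' @param train_emb Tibble with `condition`, `pc1`, `pc2` for the 7 training
#'   classes' trials (in the training-classes PCA plane).
#' @param withheld_emb Tibble with `pc1`, `pc2` for the withheld class'
#'   trials projected into the same plane.
#' @param withheld_condition The withheld class label (1..8).
#' @param ring_order Integer vector giving the ring order of all 8 classes
#'   (default 1:8).
#' @return One-row tibble of class `generalization_stats` with the four
#'   statistics.
#' @export
generalization_stats <- function(train_emb, withheld_emb, withheld_condition,
                                 ring_order = 1:8) {
  if (!withheld_condition %in% ring_order) {
    stop_bcisim("withheld condition not in the ring order",
                "bcisim_invalid_parameter")
  }
  geom <- cluster_geometry(train_emb)
  centers <- geom$centers
  if (nrow(centers) < 5) {
    stop_bcisim("need at least 5 training clusters for the ellipse",
                "bcisim_fit_error")
  }
  ell <- fit_ellipse(as.matrix(centers[, c("pc1", "pc2")]))
  gen_center <- c(mean(withheld_emb$pc1), mean(withheld_emb$pc2))

  train_d <- vapply(seq_len(nrow(centers)), function(i) {
    point_to_ellipse_distance(unlist(centers[i, c("pc1", "pc2")]),
                              ell)$distance
  }, numeric(1))
  gen_proj <- point_to_ellipse_distance(gen_center, ell)
  dist_norm <- gen_proj$distance / mean(train_d)

  gen_spread <- mean(sqrt((withheld_emb$pc1 - gen_center[1])^2 +
                          (withheld_emb$pc2 - gen_center[2])^2))
  intra_ratio <- gen_spread / mean(geom$spread)

  pos <- match(withheld_condition, ring_order)
  n_ring <- length(ring_order)
  nbrs <- ring_order[c((pos - 2) %% n_ring + 1, pos %% n_ring + 1)]
  if (!all(nbrs %in% centers$condition)) {
    stop_bcisim("ring neighbors of the withheld class are missing from the training clusters",
                "bcisim_invalid_parameter")
  }
  nbr_xy <- as.matrix(centers[match(nbrs, centers$condition),
                              c("pc1", "pc2")])
  nbr_dist <- mean(sqrt(rowSums(sweep(nbr_xy, 2, gen_center)^2)))
  D <- geom$dist_matrix
  diag(D) <- Inf
  nn <- mean(apply(D, 1, min))
  nbr_norm <- nbr_dist / nn

  thetas <- vapply(seq_len(nrow(centers)), function(i) {
    point_to_ellipse_distance(unlist(centers[i, c("pc1", "pc2")]),
                              ell)$theta
  }, numeric(1))
  names(thetas) <- centers$condition
  th_n <- thetas[as.character(nbrs)]
  th_other <- thetas[!centers$condition %in% nbrs]
  between <- angle_on_arc(gen_proj$theta, th_n[1], th_n[2], th_other)

  out <- tibble(
    withheld_condition = withheld_condition,
    dist_to_ellipse_normalized = dist_norm,
    intra_cluster_ratio = intra_ratio,
    neighbor_distance_normalized = nbr_norm,
    projects_between_neighbors = between
  )
  class(out) <- c("generalization_stats", class(out))
  out
}
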