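#' Stack trials into a trials-by-features matrix
#'
#' Concatenates each trial's channels time-major (channel 1 at all timepoints,
#' then channel 2, ...) into one row, giving a `[trials] x [channels x
#' timepoints]` matrix, the layout used for the 2D PCA projections.
#'
#' @param trials A `neural_trials` or `kinematic_trials` tibble (or any tibble
#'   with a list-column of channels-by-time matrices).
#' @param value_col Name of the list-column holding the matrices; guessed
#'   (`"rates"` then `"sensors"`) when `NULL`.
#'
#' @return Numeric matrix with one row per trial, rows in input order, row
#'   names set to `trial_id` when present.
#' @export
build_trial_matrix <- function(trials, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- intersect(c("rates", "sensors"), names(trials))[1]
    if (is.na(value_col)) {
      stop_bcisim("no `rates` or `sensors` list-column found",
                  "bcisim_invalid_parameter")
    }
  }
  mats <- trials[[value_col]]
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_bcisim("trials have inconsistent channel or step counts",
                "bcisim_shape_mismatch")
  }
  X <- t(vapply(mats, flatten_trial, numeric(prod(dims[, 1]))))
  if ("trial_id" %in% names(trials)) rownames(X) <- trials$trial_id
  attr(X, "n_channels") <- dims[1, 1]
  X
}

#' Project trials onto their top-2 principal components
#'
#' Columns are mean-centered (no variance scaling) and scores on the top two
#' right singular directions are returned. The sign of each component is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param X Trials-by-features matrix (>= 3 trials), e.g. from
#'   [build_trial_matrix()].
#' @param condition Optional integer vector of per-trial condition labels.
#' @param trial_id Optional per-trial ids (defaults to rownames or 1..n).
#'
#' @return A tibble of class `trial_embedding` with columns `trial_id`,
#'   `condition`, `pc1`, `pc2`; attributes `explained_variance` (2 fractions),
#'   `rotation` (features x 2) and `center` so new trials can be projected
#'   into the same plane.
#' @export
project_pca2 <- function(X, condition = NULL, trial_id = NULL) {
  if (nrow(X) < 3) {
    stop_bcisim("at least 3 trials are required for the PCA projection",
                "bcisim_insufficient_data")
  }
  if (is.null(trial_id)) {
    trial_id <- if (!is.null(rownames(X))) as.integer(rownames(X)) else seq_len(nrow(X))
  }
  if (is.null(condition)) condition <- rep(NA_integer_, nrow(X))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = 2)
  rot <- sv$v
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- Xc %*% rot
  ev <- sv$d^2
  ev <- ev[1:2] / sum(ev)
  out <- tibble(trial_id = trial_id, condition = condition,
                pc1 = scores[, 1], pc2 = scores[, 2])
  attr(out, "explained_variance") <- ev
  attr(out, "rotation") <- rot
  attr(out, "center") <- ctr
  class(out) <- c("trial_embedding", class(out))
  out
}

#' Project new trials into an existing embedding's plane
#'
#' @param emb A `trial_embedding` from [project_pca2()].
#' @param X New trials-by-features matrix (same feature layout).
#' @param condition,trial_id Optional labels, as in [project_pca2()].
#' @return Tibble with `trial_id`, `condition`, `pc1`, `pc2`.
#' @export
project_into_embedding <- function(emb, X, condition = NULL, trial_id = NULL) {
  rot <- attr(emb, "rotation")
  ctr <- attr(emb, "center")
  scores <- sweep(X, 2, ctr) %*% rot
  if (is.null(trial_id)) trial_id <- seq_len(nrow(X))
  if (is.null(condition)) condition <- rep(NA_integer_, nrow(X))
  tibble(trial_id = trial_id, condition = condition,
         pc1 = scores[, 1], pc2 = scores[, 2])
}

# z-score a 2-column coordinate matrix per dimension; a zero-variance
# dimension is mapped to 0 so it contributes nothing to distances.
zscore_plane <- function(xy) {
  apply(xy, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s < .Machine$double.eps) {
      rep(0, length(col))
    } else {
      (col - mean(col)) / s
    }
  })
}

#' Pair kinematic and neural trials within each condition
#'
#' For each condition, both modalities' 2D PCA coordinates are z-scored per
#' dimension across that condition's trials, a pairwise Euclidean cost matrix
#' is formed, and the linear sum assignment problem is solved (Hungarian
#' method) to pair trials so the total normalized distance is minimal.
#'
#' @param kin_emb,neu_emb `trial_embedding` tibbles (or any tibble with
#'   `trial_id`, `condition`, `pc1`, `pc2`) for the kinematic and neural
#'   trials.
#'
#' @return Tibble of class `trial_pairing` with columns `condition`,
#'   `kin_trial_id`, `neu_trial_id`, `cost` (normalized distance of the pair).
#' @export
pair_trials <- function(kin_emb, neu_emb) {
  conds <- sort(unique(kin_emb$condition))
  out <- lapply(conds, function(cc) {
    k <- kin_emb[kin_emb$condition == cc, ]
    n <- neu_emb[neu_emb$condition == cc, ]
    if (nrow(k) != nrow(n)) {
      stop_bcisim(sprintf(
        "condition %s has %d kinematic but %d neural trials; counts must match (see subsample_trials())",
        cc, nrow(k), nrow(n)), "bcisim_count_mismatch")
    }
    kz <- zscore_plane(cbind(k$pc1, k$pc2))
    nz <- zscore_plane(cbind(n$pc1, n$pc2))
    cost <- cross_dist(kz, nz)
    sol <- clue::solve_LSAP(cost)
    j <- as.integer(sol)
    tibble(condition = cc,
           kin_trial_id = k$trial_id,
           neu_trial_id = n$trial_id[j],
           cost = cost[cbind(seq_len(nrow(cost)), j)])
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("trial_pairing", class(out))
  out
}

#' Subsample trials so per-condition counts match a reference
#'
#' Deterministic (seeded) helper for the case where one modality has more
#' trials per condition than the other.
#'
#' @param trials A trials tibble with a `condition` column.
#' @param n_per_condition Named or unnamed vector of counts (recycled), or a
#'   single count.
#' @param seed Integer seed.
#' @return The subsampled trials tibble (original attributes preserved).
#' @export
subsample_trials <- function(trials, n_per_condition, seed = 1L) {
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$condition),
                        function(idx) {
    n <- if (length(n_per_condition) == 1L) n_per_condition
         else n_per_condition[[as.character(trials$condition[idx[1]])]]
    if (length(idx) < n) {
      stop_bcisim("fewer trials than requested in a condition",
                  "bcisim_count_mismatch")
    }
    sort(sample(idx, n))
  }))
  out <- trials[sort(keep), ]
  for (a in setdiff(names(attributes(trials)),
                    c("names", "row.names", "class"))) {
    attr(out, a) <- attr(trials, a)
  }
  out
}

#' Pair several kinematic datasets with one neural session
#'
#' Runs [pair_trials()] independently for each kinematic dataset (one per
#' replicated subject) against the same neural session and concatenates the
#' resulting pairs, so each neural trial appears once per subject dataset.
#' Replication teaches the emulator that across-subject kinematic variation
#' is noise, not structure.
#'
#' @param kin_embs List of kinematic `trial_embedding` tibbles (one per
#'   subject).
#' @param neu_emb Neural `trial_embedding` tibble.
#' @return `trial_pairing` tibble with an extra `subject` column (index into
#'   `kin_embs`, or the list's names when set).
#' @export
replicate_pairings <- function(kin_embs, neu_emb) {
  if (length(kin_embs) < 1) {
    stop_bcisim("need at least one kinematic dataset",
                "bcisim_invalid_parameter")
  }
  labs <- names(kin_embs)
  if (is.null(labs)) labs <- as.character(seq_along(kin_embs))
  out <- purrr::map2(kin_embs, labs, function(ke, lab) {
    p <- pair_trials(ke, neu_emb)
    p$subject <- lab
    p
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("trial_pairing", class(out))
  out
}
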