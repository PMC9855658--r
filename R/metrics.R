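# The seven standard center-out behavioral measures, computed from cursor
# trajectories: ER, MDC, ODC, ME, MV, MT, DR.

# Signed orthogonal distances of trajectory points to the start->target line.
signed_offsets <- function(traj, start, target) {
  seg <- target - start
  len <- sqrt(sum(seg^2))
  if (len < .Machine$double.eps) {
    stop_bcisim("start and target coincide; offsets are undefined",
                "bcisim_geometry_error")
  }
  u <- seg / len
  nrm <- c(-u[2], u[1])
  (traj[, 1] - start[1]) * nrm[1] + (traj[, 2] - start[2]) * nrm[2]
}

#' Movement error (ME)
#'
#' Average absolute distance of the cursor to the straight line joining the
#' start position and the target.
#'
#' @param traj `N x 2` matrix of cursor positions (cm), go cue to trial end.
#' @param start,target Length-2 positions (cm).
#' @return ME in cm.
#' @export
movement_error <- function(traj, start, target) {
  if (nrow(traj) < 2) {
    stop_bcisim("need at least 2 trajectory points", "bcisim_geometry_error")
  }
  mean(abs(signed_offsets(traj, start, target)))
}

#' Movement variation (MV)
#'
#' Sample standard deviation (denominator N - 1) of the signed orthogonal
#' distances of trajectory points to the start->target line.
#'
#' @inheritParams movement_error
#' @return MV in cm.
#' @export
movement_variation <- function(traj, start, target) {
  if (nrow(traj) < 2) {
    stop_bcisim("need at least 2 trajectory points", "bcisim_geometry_error")
  }
  sd(signed_offsets(traj, start, target))
}

# Count sign changes with a dead band: components smaller than `deadband`
# carry the previous sign, avoiding noise-driven counts.
count_sign_changes <- function(x, deadband = 1e-6) {
  s <- 0
  n <- 0L
  for (v in x) {
    cur <- if (abs(v) >= deadband) sign(v) else s
    if (s != 0 && cur != 0 && cur != s) n <- n + 1L
    s <- cur
  }
  n
}

#' Direction changes perpendicular and parallel to the ideal path
#'
#' Decomposes per-tick cursor velocity into components perpendicular (MDC)
#' and parallel (ODC) to the start->target line and counts sign changes of
#' each component, one count per sign flip.
#'
#' @inheritParams movement_error
#' @param deadband Components with absolute value below this carry the
#'   previous sign (default 1e-6 cm/tick).
#' @return Named list with integers `MDC` and `ODC`.
#' @export
direction_changes <- function(traj, start, target, deadband = 1e-6) {
  if (nrow(traj) < 3) {
    stop_bcisim("need at least 3 trajectory points", "bcisim_geometry_error")
  }
  seg <- target - start
  len <- sqrt(sum(seg^2))
  if (len < .Machine$double.eps) {
    stop_bcisim("start and target coincide", "bcisim_geometry_error")
  }
  u <- seg / len
  nrm <- c(-u[2], u[1])
  v <- diff(traj)
  par <- v[, 1] * u[1] + v[, 2] * u[2]
  perp <- v[, 1] * nrm[1] + v[, 2] * nrm[2]
  list(MDC = count_sign_changes(perp, deadband),
       ODC = count_sign_changes(par, deadband))
}

#' Distance ratio (DR)
#'
#' Trajectory path length divided by the straight-line distance between the
#' first and last cursor positions; at least 1 for distinct endpoints.
#'
#' @param traj `N x 2` matrix of cursor positions (cm).
#' @return DR (dimensionless), or `NA` with a warning when the endpoints
#'   coincide.
#' @export
distance_ratio <- function(traj) {
  path <- sum(sqrt(rowSums(diff(traj)^2)))
  chord <- sqrt(sum((traj[nrow(traj), ] - traj[1, ])^2))
  if (chord < .Machine$double.eps) {
    warning("coincident trajectory endpoints; DR undefined")
    return(NA_real_)
  }
  path / chord
}

#' Error rate (ER)
#'
#' Fraction of trials whose hit (dwell completion) occurs after the
#' error-rate time criterion or not at all.
#'
#' @param trials Tibble with `outcome` ("hit"/"miss") and `movement_time`
#'   columns (one row per trial).
#' @param threshold Time criterion in seconds (default 6.5).
#' @return Fraction in \[0, 1\].
#' @export
error_rate <- function(trials, threshold = 6.5) {
  if (nrow(trials) < 1) {
    stop_bcisim("need at least one trial", "bcisim_invalid_parameter")
  }
  late <- trials$outcome != "hit" |
    (is.finite(trials$movement_time) & trials$movement_time > threshold)
  mean(late)
}

#' Movement time (MT) of a hit trial
#'
#' Time from go cue to dwell completion, including the 500 ms dwell. Misses
#' yield `NA` and are excluded from visit-level MT aggregation.
#'
#' @param movement_time Recorded time, s.
#' @param outcome "hit" or "miss".
#' @return MT in seconds or `NA_real_`.
#' @export
movement_time <- function(movement_time, outcome) {
  if (outcome != "hit") return(NA_real_)
  movement_time
}

#' All per-trial trajectory metrics
#'
#' @param traj `N x 2` cursor positions from the go cue to trial end
#'   (including dwell ticks).
#' @param start,target Length-2 positions (cm).
#' @param outcome "hit" or "miss".
#' @param movement_time Time to dwell completion, s (NA for a miss).
#' @param dt Tick period, s.
#' @return One-row tibble with ME, MV, MDC, ODC, DR, MT.
#' @export
trial_metrics <- function(traj, start, target, outcome = "hit",
                          movement_time = NA_real_, dt = 0.025) {
  dc <- direction_changes(traj, start, target)
  tibble(
    ME = movement_error(traj, start, target),
    MV = movement_variation(traj, start, target),
    MDC = dc$MDC, ODC = dc$ODC,
    DR = suppressWarnings(distance_ratio(traj)),
    MT = if (outcome == "hit") movement_time else NA_real_
  )
}

#' Pairwise correlations between behavioral measures
#'
#' Pearson correlations (with two-sided p-values) between subject-mean
#' behavioral measures across visit summaries.
#'
#' @param summaries Tibble with one row per visit/subject summary and the
#'   metric columns.
#' @param metrics Character vector of columns to correlate.
#' @return Tibble with `metric_a`, `metric_b`, `r`, `p` for each pair;
#'   constant columns yield `NA` with a warning.
#' @export
metric_correlations <- function(summaries,
                                metrics = c("MV", "ME", "MT", "MDC", "ODC")) {
  if (nrow(summaries) < 3) {
    stop_bcisim("need at least 3 summaries", "bcisim_invalid_parameter")
  }
  combos <- utils::combn(metrics, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- summaries[[combos[1, i]]]
    b <- summaries[[combos[2, i]]]
    ok <- is.finite(a) & is.finite(b)
    if (sd(a[ok]) < .Machine$double.eps || sd(b[ok]) < .Machine$double.eps) {
      warning(sprintf("constant column in %s-%s; correlation undefined",
                      combos[1, i], combos[2, i]))
      return(tibble(metric_a = combos[1, i], metric_b = combos[2, i],
                    r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(a[ok], b[ok])
    tibble(metric_a = combos[1, i], metric_b = combos[2, i],
           r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Learning-corrected per-session performance
#'
#' Removes the across-visit learning curve by subtracting each visit's mean
#' score over all subjects, then averages the corrected scores by emulator
#' session and reports the spread across sessions.
#'
#' @param summaries Tibble with `visit`, `session_id` and `score` columns
#'   (e.g. targets hit).
#' @return List with `per_session` (tibble: session_id, mean corrected score,
#'   n) and `sd_across_sessions`.
#' @export
learning_corrected_session_effect <- function(summaries) {
  stopifnot(all(c("visit", "session_id", "score") %in% names(summaries)))
  if (length(unique(summaries$visit)) < 2) {
    stop_bcisim("need at least 2 visits", "bcisim_invalid_parameter")
  }
  corrected <- summaries |>
    dplyr::group_by(.data$visit) |>
    dplyr::mutate(corrected = .data$score - mean(.data$score)) |>
    dplyr::ungroup()
  per_session <- corrected |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(mean_corrected = mean(.data$corrected),
                     n = dplyr::n(), .groups = "drop")
  if (nrow(per_session) < 2) {
    stop_bcisim("need at least 2 sessions for a spread",
                "bcisim_invalid_parameter")
  }
  list(per_session = per_session,
       sd_across_sessions = sd(per_session$mean_corrected))
}
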