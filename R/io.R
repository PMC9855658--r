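# File-format schemas and atomic readers/writers for every pipeline artifact.
# All formats are plain text (CSV / JSON / JSON-lines); writes go through a
# temp file + rename so partially written artifacts are never observed.

atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_bcisim(sprintf("could not move temporary file onto '%s'", path),
                "bcisim_io_error")
  }
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_bcisim(sprintf("'%s' is missing required column(s): %s", path,
                        paste(missing, collapse = ", ")),
                "bcisim_schema_error")
  }
  invisible(df)
}

#' Write / read a neural session as long-format CSV plus a JSON manifest
#'
#' The CSV has one row per (trial, neuron, timestep); the manifest records
#' the session id, sizes, seed and generator parameters, with a schema
#' version field.
#'
#' @param trials A `neural_trials` tibble.
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(trials, path) {
  time <- attr(trials, "time")
  long <- purrr::pmap_dfr(
    trials[c("trial_id", "condition", "rates")],
    function(trial_id, condition, rates) {
      tibble(trial_id = trial_id, condition = condition,
             neuron = rep(seq_len(nrow(rates)), times = ncol(rates)),
             step = rep(seq_len(ncol(rates)), each = nrow(rates)),
             rate = as.numeric(rates))
    })
  write_csv_atomic(long, path)
  spec <- attr(trials, "spec")
  gen <- attr(trials, "generator")
  manifest <- list(
    schema_version = 1L,
    session_id = trials$session_id[1],
    n_neurons = nrow(trials$rates[[1]]),
    n_trials = nrow(trials),
    n_steps = ncol(trials$rates[[1]]),
    time = time,
    seed = if (!is.null(spec)) spec$seed else NA,
    generator = if (!is.null(gen)) {
      gen[c("latent_dim", "rotation_strength", "latent_noise_sd")]
    }
  )
  atomic_write(paste0(path, ".manifest.json"), function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  long <- utils::read.csv(path)
  require_columns(long, c("trial_id", "condition", "neuron", "step", "rate"),
                  path)
  man_path <- paste0(path, ".manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path,
                                                        simplifyVector = TRUE)
  ids <- sort(unique(long$trial_id))
  rows <- lapply(ids, function(id) {
    sub <- long[long$trial_id == id, ]
    n_n <- max(sub$neuron)
    m <- matrix(0, n_n, max(sub$step))
    m[cbind(sub$neuron, sub$step)] <- sub$rate
    tibble(session_id = man$session_id %||% "unknown", trial_id = id,
           condition = sub$condition[1], rates = list(m))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(man$time)) attr(out, "time") <- man$time
  class(out) <- c("neural_trials", class(out))
  out
}

#' Write / read kinematic trials as long-format CSV
#'
#' Columns: `trial_id`, `condition`, `step`, `s01`..`s19`.
#'
#' @param trials A `kinematic_trials` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(trials, path) {
  long <- purrr::pmap_dfr(
    trials[c("trial_id", "condition", "sensors")],
    function(trial_id, condition, sensors) {
      wide <- as.data.frame(t(sensors))
      names(wide) <- sprintf("s%02d", seq_len(nrow(sensors)))
      dplyr::bind_cols(tibble(trial_id = trial_id, condition = condition,
                              step = seq_len(ncol(sensors))), wide)
    })
  long$subject_id <- trials$subject_id[1]
  write_csv_atomic(long, path)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path) {
  long <- utils::read.csv(path)
  require_columns(long, c("trial_id", "condition", "step", "s01"), path)
  scols <- grep("^s[0-9]{2}$", names(long), value = TRUE)
  ids <- sort(unique(long$trial_id))
  rows <- lapply(ids, function(id) {
    sub <- long[long$trial_id == id, ]
    sub <- sub[order(sub$step), ]
    tibble(subject_id = if ("subject_id" %in% names(long))
             sub$subject_id[1] else "unknown",
           trial_id = id, condition = sub$condition[1],
           sensors = list(t(as.matrix(sub[, scols]))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kinematic_trials", class(out))
  out
}

#' Write / read a trial pairing as CSV
#' @param pairing A `trial_pairing` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pairing_csv <- function(pairing, path) {
  write_csv_atomic(as.data.frame(pairing), path)
  invisible(path)
}

#' @rdname write_pairing_csv
#' @export
read_pairing_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("condition", "kin_trial_id", "neu_trial_id", "cost"),
                  path)
  out <- as_tibble(df)
  class(out) <- c("trial_pairing", class(out))
  out
}

#' Write / read an emulator checkpoint (JSON)
#'
#' Single JSON archive holding the encoder weights, the readout bank keyed
#' by session id, the architecture configuration and the training log.
#'
#' @param net An `emulator_net`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_emulator <- function(net, path) {
  payload <- list(
    schema_version = 1L,
    config = unclass(net$config),
    encoder = lapply(net$encoder, function(m) {
      list(dim = dim(m) %||% length(m), data = as.numeric(m))
    }),
    readouts = lapply(net$readouts, function(r) {
      lapply(r[c("Wh", "bh", "Wo", "bo")], function(m) {
        list(dim = dim(m) %||% length(m), data = as.numeric(m))
      })
    }),
    active_session = net$active_session,
    seed = net$seed,
    train_log = if (!is.null(net$train_log)) as.list(net$train_log),
    best_round = net$best_round
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

unpack_mat <- function(x) {
  if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2]) else x$data
}

#' @rdname write_emulator
#' @export
read_emulator <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(p$encoder) || is.null(p$readouts)) {
    stop_bcisim(sprintf("'%s' is not an emulator checkpoint", path),
                "bcisim_schema_error")
  }
  cfg <- p$config
  config <- emulator_config(n_lags = cfg$n_lags, n_sensors = cfg$n_sensors,
                            encoder_widths = unlist(cfg$encoder_widths),
                            readout_hidden_width = cfg$readout_hidden_width,
                            dt = cfg$dt)
  net <- structure(
    list(config = config,
         encoder = lapply(p$encoder, unpack_mat),
         readouts = lapply(p$readouts, function(r) lapply(r, unpack_mat)),
         active_session = p$active_session, seed = p$seed,
         train_log = if (!is.null(p$train_log)) as_tibble(p$train_log),
         best_round = p$best_round),
    class = "emulator_net")
  net
}

#' Write / read a decoder checkpoint (JSON)
#'
#' Archives A, W, H, Q, the steady-state gain K and covariance P, the state
#' layout and the session id.
#'
#' @param model A [kalman_model()] (gain computed).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_decoder <- function(model, path) {
  mats <- lapply(model[c("A", "W", "H", "Q", "K", "P", "P_prior")],
                 function(m) if (is.null(m)) NULL else
                   list(dim = dim(m), data = as.numeric(m)))
  payload <- list(schema_version = 1L, matrices = mats, dt = model$dt,
                  state_layout = c("Vx", "Vy", "offset"),
                  session_id = attr(model, "session_id"))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(p$matrices)) {
    stop_bcisim(sprintf("'%s' is not a decoder checkpoint", path),
                "bcisim_schema_error")
  }
  m <- lapply(p$matrices, unpack_mat)
  model <- kalman_model(m$A, m$W, m$H, m$Q, dt = p$dt)
  model$K <- m$K; model$P <- m$P; model$P_prior <- m$P_prior
  attr(model, "session_id") <- p$session_id
  model
}

#' Write / read closed-loop trial logs as JSON-lines
#'
#' One JSON record per tick, each carrying the trial id, tick time, cursor
#' position, decoded velocity and in-target flag.
#'
#' @param trials The `trials` tibble from [run_visit()].
#' @param path Output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_trial_logs <- function(trials, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(trials))) {
      traj <- trials$trajectory[[i]]
      for (k in seq_len(nrow(traj))) {
        rec <- list(trial = trials$trial[i], target = trials$target[i],
                    outcome = trials$outcome[i], tick = k,
                    x = traj[k, 1], y = traj[k, 2])
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
    }
  })
  invisible(path)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- dplyr::bind_rows(recs)
  require_columns(df, c("trial", "target", "outcome", "tick", "x", "y"), path)
  as_tibble(df)
}

#' Checksum manifest for emitted artifacts
#'
#' @param paths Character vector of files.
#' @return Tibble with `file` and `md5`.
#' @export
artifact_manifest <- function(paths) {
  tibble(file = basename(paths),
         md5 = unname(tools::md5sum(paths)))
}

#' Verify files against a manifest
#'
#' @param dir Directory holding the artifacts.
#' @param manifest A tibble from [artifact_manifest()].
#' @return Invisibly TRUE; mismatches raise an error naming the file.
#' @export
verify_artifacts <- function(dir, manifest) {
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    got <- unname(tools::md5sum(f))
    if (is.na(got) || got != manifest$md5[i]) {
      stop_bcisim(sprintf("checksum mismatch for artifact '%s'",
                          manifest$file[i]),
                  "bcisim_checksum_error")
    }
  }
  invisible(TRUE)
}
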