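# End-to-end experiment driver: simulate-data -> pair -> train -> calibrate
# -> run -> validate -> metrics, with artifacts and a checksum manifest.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    synthetic = list(
      n_sessions = 3L, n_neurons = c(30L, 45L, 60L),
      n_trials_per_condition = 20L, n_conditions = 8L,
      latent_dim = 6L, rotation_strength = 2 * pi, latent_noise_sd = 0.08
    ),
    kinematics = list(
      n_subjects = 4L, duration = 1.2, ring_radius = 0.25,
      motor_noise_sd = 0.02
    ),
    emulator = list(
      train_fraction = 0.85, steps_per_visit = 300L, max_rounds = 3L,
      batch_size = 1024L, lr = 2e-3
    ),
    task = list(trials_per_visit = 80L, n_targets = 4L),
    closed_loop = list(n_subjects = 2L, n_visits = 2L),
    validation = list(n_perm = 999L)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop_bcisim(sprintf("unknown configuration key '%s%s'", path, nm),
                  "bcisim_config_error")
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build an experiment configuration
#'
#' Nested configuration for the full pipeline. Defaults are desk-scale
#' (3 sessions of 30/45/60 neurons, 20 trials per condition, 4 replicated
#' kinematic subjects, 2 closed-loop subjects x 2 visits). Unknown keys are
#' rejected. Round-trips losslessly through JSON.
#'
#' @param ... Named overrides, nested lists mirroring the default structure
#'   (`seed`, `out_dir`, `synthetic`, `kinematics`, `emulator`, `task`,
#'   `closed_loop`, `validation`).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- merge_config(default_config(), list(...))
  structure(cfg, class = "experiment_config")
}

#' Serialize / deserialize an experiment configuration
#' @param config An [experiment_config()].
#' @param path JSON file path.
#' @return `read_experiment_config` returns the configuration.
#' @export
write_experiment_config <- function(config, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$synthetic$n_neurons <- as.integer(raw$synthetic$n_neurons)
  # an unset out_dir serializes as an empty container
  if (length(raw$out_dir) == 0) raw$out_dir <- NULL
  do.call(experiment_config, raw)
}

#' Simulate the full study inputs
#'
#' Generates the synthetic neural sessions and the replicated kinematic
#' subject datasets specified by a configuration.
#'
#' @param config An [experiment_config()].
#' @return List with `sessions` (named list of `neural_trials`), `kinematics`
#'   (named list of `kinematic_trials`) and `postures`.
#' @export
simulate_study_data <- function(config) {
  sc <- config$synthetic
  kc <- config$kinematics
  n_neurons <- rep(sc$n_neurons, length.out = sc$n_sessions)
  sessions <- lapply(seq_len(sc$n_sessions), function(i) {
    spec <- session_spec(
      session_id = sprintf("S%02d", i), n_neurons = n_neurons[i],
      n_trials_per_condition = sc$n_trials_per_condition,
      n_conditions = sc$n_conditions, seed = config$seed + i)
    generate_neural_session(spec, latent_dim = sc$latent_dim,
                            rotation_strength = sc$rotation_strength,
                            latent_noise_sd = sc$latent_noise_sd)
  })
  names(sessions) <- vapply(sessions, function(s) s$session_id[1],
                            character(1))
  postures <- posture_set(seed = config$seed,
                          n_targets = sc$n_conditions,
                          ring_radius = kc$ring_radius,
                          motor_noise_sd = kc$motor_noise_sd)
  kinematics <- lapply(seq_len(kc$n_subjects), function(j) {
    generate_kinematic_trials(
      postures, n_reps = sc$n_trials_per_condition, duration = kc$duration,
      seed = config$seed + 1000L + j, subject_id = sprintf("P%02d", j))
  })
  names(kinematics) <- vapply(kinematics, function(k) k$subject_id[1],
                              character(1))
  list(sessions = sessions, kinematics = kinematics, postures = postures)
}

#' Run the full experiment end to end
#'
#' Executes simulate-data, pairing, emulator training, then per-subject
#' visits (calibration + closed-loop task), the neural-statistics validation
#' and the behavioral metrics, writing every artifact under
#' `config$out_dir` and returning a checksum manifest. Fully deterministic
#' under `config$seed`.
#'
#' @param config An [experiment_config()] with `out_dir` set.
#' @return List with `manifest` (tibble of artifacts and md5 sums),
#'   `visit_summaries`, `validation` (per-session Mantel and jPCA
#'   summaries), `net` and `data`.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (is.null(config$out_dir)) {
    stop_bcisim("config$out_dir must be set", "bcisim_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(p) paths[[length(paths) + 1]] <<- p

  # stage 1: simulate
  data <- simulate_study_data(config)
  for (nm in names(data$sessions)) {
    emit(write_session_csv(data$sessions[[nm]],
                           file.path(config$out_dir,
                                     sprintf("session_%s.csv", nm))))
  }
  for (nm in names(data$kinematics)) {
    emit(write_kinematics_csv(data$kinematics[[nm]],
                              file.path(config$out_dir,
                                        sprintf("kinematics_%s.csv", nm))))
  }

  # stage 2: pair
  pairs <- make_paired_dataset(data$kinematics, data$sessions)
  emit(write_pairing_csv(
    pairs[c("session_id", "subject", "condition", "kin_trial_id",
            "neu_trial_id")],
    file.path(config$out_dir, "pairing.csv")))

  # stage 3: train
  ec <- config$emulator
  split <- split_train_validation(pairs, fraction = ec$train_fraction,
                                  seed = config$seed)
  control <- emulator_control(batch_size = ec$batch_size, lr = ec$lr,
                              steps_per_visit = ec$steps_per_visit,
                              max_rounds = ec$max_rounds)
  net <- train_emulator(split$train, seed = config$seed, control = control)
  emit(write_emulator(net, file.path(config$out_dir, "emulator.json")))

  # stage 4: closed-loop visits
  tc <- do.call(task_config, config$task)
  cl <- config$closed_loop
  summaries <- list()
  for (j in seq_len(cl$n_subjects)) {
    plan <- visit_plan(sprintf("U%02d", j), names(data$sessions),
                       n_visits = cl$n_visits,
                       seed = config$seed + 2000L + j)
    for (v in seq_len(nrow(plan))) {
      res <- run_visit(net, plan$session_id[v], data$postures, tc,
                       seed = plan$seed[v])
      emit(write_decoder(res$model,
                         file.path(config$out_dir,
                                   sprintf("decoder_%s_v%d.json",
                                           plan$subject_id[v], v))))
      emit(write_trial_logs(res$trials,
                            file.path(config$out_dir,
                                      sprintf("trials_%s_v%d.jsonl",
                                              plan$subject_id[v], v))))
      summaries[[length(summaries) + 1]] <-
        dplyr::bind_cols(tibble(subject_id = plan$subject_id[v], visit = v),
                         res$summary)
    }
  }
  visit_summaries <- dplyr::bind_rows(summaries)

  # stage 5: validation statistics per session
  validation <- lapply(names(data$sessions), function(nm) {
    ses <- data$sessions[[nm]]
    net_s <- set_active_session(net, nm)
    kin <- data$kinematics[[1]]
    n_steps <- ncol(ses$rates[[1]])
    emu <- kin
    emu$rates <- lapply(kin$sensors, function(s) {
      emulate_trial(net_s, resample_trial(s, n_steps))
    })
    emu$sensors <- NULL
    class(emu) <- c("neural_trials", class(emu))
    attr(emu, "time") <- attr(ses, "time")
    g_real <- cluster_geometry(project_pca2(build_trial_matrix(ses),
                                            ses$condition, ses$trial_id))
    g_emu <- cluster_geometry(project_pca2(build_trial_matrix(emu),
                                           emu$condition, emu$trial_id))
    mt <- mantel_test(g_real$dist_matrix, g_emu$dist_matrix,
                      n_perm = config$validation$n_perm, seed = config$seed)
    jp <- jpca(ses)
    tibble(session_id = nm, mantel_r = mt$r, mantel_p = mt$p,
           jpca_top_freq = jp$freq[1], jpca_top_var = jp$var_captured[1])
  })
  validation <- dplyr::bind_rows(validation)
  emit(atomic_write(file.path(config$out_dir, "validation.json"),
                    function(tmp) {
    jsonlite::write_json(validation, tmp, auto_unbox = TRUE, digits = NA)
  }))

  # stage 6: metrics (wall-clock columns stay out of the artifact so equal
  # seeds give byte-identical files)
  metrics_out <- visit_summaries[setdiff(names(visit_summaries),
                                         "tick_compute")]
  emit(write_csv_atomic(as.data.frame(metrics_out),
                        file.path(config$out_dir, "visit_metrics.csv")))
  if (nrow(visit_summaries) >= 3) {
    mc <- metric_correlations(visit_summaries)
    emit(write_csv_atomic(as.data.frame(mc),
                          file.path(config$out_dir,
                                    "metric_correlations.csv")))
  }

  manifest <- artifact_manifest(unlist(paths))
  atomic_write(file.path(config$out_dir, "manifest.json"), function(tmp) {
    jsonlite::write_json(list(schema_version = 1L, seed = config$seed,
                              artifacts = manifest),
                         tmp, auto_unbox = TRUE, digits = NA)
  })
  list(manifest = manifest, visit_summaries = visit_summaries,
       validation = validation, net = net, data = data)
}
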