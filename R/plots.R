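# ggplot2 visualisations for the main result types.

#' @method autoplot trial_embedding
#' @export
autoplot.trial_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                       colour = factor(.data$condition))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "condition",
                  title = "Trial projection on the top-2 PCA plane") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot jpca_result
#' @export
autoplot.jpca_result <- function(object, plane = 1, ...) {
  df <- object$trajectories[object$trajectories$plane == plane, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$jpc1, y = .data$jpc2,
                                   colour = factor(.data$condition))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = sprintf("jPC%d", 2 * plane - 1),
                  y = sprintf("jPC%d", 2 * plane),
                  colour = "condition",
                  title = sprintf(
                    "jPCA plane %d (%.2f Hz, %.0f%% variance)", plane,
                    object$freq[plane] / (2 * pi),
                    100 * object$var_captured[plane])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot closed-loop cursor trajectories for a visit
#'
#' @param trials The `trials` tibble from [run_visit()].
#' @param config The [task_config()] used (draws the targets).
#' @return A ggplot object.
#' @export
plot_visit_trajectories <- function(trials, config = task_config()) {
  tp <- as.data.frame(target_positions(config))
  tp$target <- seq_len(nrow(tp))
  df <- purrr::pmap_dfr(trials[c("trial", "target", "trajectory", "outcome")],
                        function(trial, target, trajectory, outcome) {
    tibble(trial = trial, target = target, outcome = outcome,
           x = trajectory[, 1], y = trajectory[, 2])
  })
  half <- config$target_size / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$trial,
                                   colour = factor(.data$target))) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_rect(data = tp, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$x - half,
                                    xmax = .data$x + half,
                                    ymin = .data$y - half,
                                    ymax = .data$y + half),
                       fill = NA, colour = "grey30") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "target",
                  title = "Closed-loop cursor trajectories") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot peri-event rate averages for selected neurons
#'
#' @param pe Result of [perievent_average()].
#' @param neurons Neuron indices to display (default first 2).
#' @return A ggplot object.
#' @export
plot_perievent <- function(pe, neurons = 1:2) {
  df <- pe$means[pe$means$neuron %in% neurons, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$rate,
                                   colour = factor(.data$condition))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~neuron, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time from go cue (s)", y = "rate (spikes/s)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
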