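#' Plot normalised performance across capacity conditions
#'
#' Mean normalised performance (points, one SD error bars) against memory
#' capacity fraction, coloured by encoding and faceted by layout — the
#' standard capacity-ladder view of an experiment. An optional chance level
#' (random-walk baseline) is drawn as a dotted line.
#'
#' @param object An `experiment_result`.
#' @param chance_level Optional normalised-performance chance level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, chance_level = NULL, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$fraction),
                                       y = .data$mean_performance,
                                       colour = .data$encoding,
                                       group = .data$encoding)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_performance - .data$sd_performance,
      ymax = .data$mean_performance + .data$sd_performance),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.4),
                       alpha = 0.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$rule),
                        cols = ggplot2::vars(.data$layout)) +
    ggplot2::labs(x = "memory capacity (fraction of available states)",
                  y = "normalised performance (%)", colour = "encoding")
  if (!is.null(chance_level)) {
    p <- p + ggplot2::geom_hline(yintercept = chance_level, linetype = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a per-state field
#'
#' Generic tile map over grid coordinates for any per-state scalar
#' (entropy, forgetting incidence, incidence difference, ...). Obstacles of
#' the supplied environment are drawn in dark grey.
#'
#' @param field A tibble with `x`, `y` and the plotted column.
#' @param value Column to plot (tidy-eval).
#' @param env Optional `gridworld` whose obstacles and reward are overlaid.
#' @param diverging Use a diverging palette centred at 0 (for difference
#'   fields).
#' @return A ggplot object.
#' @export
plot_state_field <- function(field, value, env = NULL, diverging = FALSE) {
  value <- rlang::enquo(value)
  p <- ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = !!value)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (diverging) {
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                           high = "#b2182b", midpoint = 0)
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  if (!is.null(env)) {
    if (nrow(env$obstacles) > 0) {
      p <- p + ggplot2::geom_tile(data = env$obstacles, fill = "grey20")
    }
    p <- p + ggplot2::annotate("point", x = env$reward_state[1],
                               y = env$reward_state[2], shape = 0, size = 3)
  }
  p
}

#' Preferred-direction vector field
#'
#' Draws each state's preferred-direction vector as an arrow scaled by
#' `scale`, the standard visualisation of policy coherence.
#'
#' @param field A tibble with `x`, `y`, `zx`, `zy` (see
#'   [average_policy_fields()] or [policy_map()]).
#' @param env Optional `gridworld` for obstacle/reward overlay.
#' @param scale Arrow length multiplier.
#' @return A ggplot object.
#' @export
plot_direction_field <- function(field, env = NULL, scale = 0.8) {
  p <- ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + scale * .data$zx,
                   yend = .data$y + scale * .data$zy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.04, "inches")),
      linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(env)) {
    if (nrow(env$obstacles) > 0) {
      p <- p + ggplot2::geom_tile(data = env$obstacles, fill = "grey20")
    }
    p <- p + ggplot2::annotate("point", x = env$reward_state[1],
                               y = env$reward_state[2], shape = 0, size = 3)
  }
  p
}
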