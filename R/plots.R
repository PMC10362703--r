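# ggplot2 displays for fitted objects.

#' Plot the reward trace of a structure search
#'
#' Best-so-far and per-iteration mean rewards against iteration.
#'
#' @param object A `causal_rl_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.causal_rl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("best_reward", "mean_reward"),
                              names_to = "series", values_to = "reward")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$reward,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(best_reward = "#D55E00", mean_reward = "grey40"),
      labels = c(best_reward = "best so far", mean_reward = "batch mean")
    ) +
    ggplot2::labs(x = "iteration", y = "reward", colour = NULL,
                  title = "Structure-search reward trace") +
    ggplot2::theme_minimal()
}

#' Plot a weighted causal graph
#'
#' Variables on a circle, directed edges as arrows labeled with their
#' inverse-information-entropy strength.
#'
#' @param object A `weighted_causal_graph`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.weighted_causal_graph <- function(object, ...) {
  vars <- object$variables
  d <- length(vars)
  theta <- 2 * pi * (seq_len(d) - 1) / d
  nodes <- tibble::tibble(name = vars, x = cos(theta), y = sin(theta))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Weighted causal graph")
  if (nrow(object$edges) > 0) {
    e <- object$edges
    i <- match(e$from, vars)
    j <- match(e$to, vars)
    shrink <- 0.12   # pull arrows off the node markers
    seg <- tibble::tibble(
      x = nodes$x[i] + shrink * (nodes$x[j] - nodes$x[i]),
      y = nodes$y[i] + shrink * (nodes$y[j] - nodes$y[i]),
      xend = nodes$x[j] - shrink * (nodes$x[j] - nodes$x[i]),
      yend = nodes$y[j] - shrink * (nodes$y[j] - nodes$y[i]),
      label = formatC(e$strength, format = "g", digits = 3)
    )
    p <- p +
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
        colour = "grey30"
      ) +
      ggplot2::geom_label(
        data = seg,
        ggplot2::aes(x = (.data$x + .data$xend) / 2,
                     y = (.data$y + .data$yend) / 2, label = .data$label),
        size = 3, label.size = 0
      )
  }
  p +
    ggplot2::geom_point(size = 10, colour = "#0072B2") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), colour = "white",
                       size = 3)
}

#' @rdname autoplot.causal_rl_fit
#' @export
plot_reward_trace <- function(object, ...) autoplot.causal_rl_fit(object, ...)

#' @rdname autoplot.weighted_causal_graph
#' @export
plot_causal_graph <- function(object, ...) {
  autoplot.weighted_causal_graph(object, ...)
}
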