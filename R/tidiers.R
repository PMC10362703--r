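# broom-style tidiers for fitted objects.

#' Tidy a reinforcement-learning structure-search fit
#'
#' @param x A `causal_rl_fit`.
#' @param type `"trace"` (default) returns the per-iteration reward trace;
#'   `"graphs"` returns one row per distinct graph scored during the run.
#' @param ... Unused.
#'
#' @return A tibble.
#' @export
tidy.causal_rl_fit <- function(x, type = c("trace", "graphs"), ...) {
  type <- match.arg(type)
  switch(type, trace = x$trace, graphs = x$graph_log)
}

#' One-row summary of a structure-search fit
#'
#' @param x A `causal_rl_fit`.
#' @param ... Unused.
#'
#' @return A one-row tibble: iteration/graph counts and the best graph's
#'   score components.
#' @export
glance.causal_rl_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$config$iterations,
    graphs_per_iteration = x$config$graphs_per_iteration,
    graphs_scored = nrow(x$graph_log),
    best_bic = x$best$bic,
    best_h = x$best$h,
    best_is_dag = x$best$is_dag,
    best_reward = x$best$reward,
    best_edges = sum(x$best$graph[[1]])
  )
}

#' Tidy a weighted causal graph
#'
#' @param x A `weighted_causal_graph`.
#' @param ... Unused.
#'
#' @return The edge tibble (`from`, `to`, `strength`).
#' @export
tidy.weighted_causal_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a weighted causal graph
#'
#' @param x A `weighted_causal_graph`.
#' @param ... Unused.
#'
#' @return A one-row tibble with variable and edge counts, the pruning
#'   threshold, and the mean retained strength.
#' @export
glance.weighted_causal_graph <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    n_edges = nrow(x$edges),
    n_edges_before = x$n_edges_before,
    threshold = x$threshold,
    mean_strength = if (nrow(x$edges) > 0) mean(x$edges$strength) else NA_real_
  )
}
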