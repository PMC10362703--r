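# End-to-end orchestration: read -> normalize -> RL structure search ->
# strength annotation and pruning -> outputs.

#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run. Sub-configurations follow
#' [training_config()], [encoder_config()] and [reward_config()]; the
#' top-level `seed` overrides the training seed so one integer controls the
#' whole run.
#'
#' @param input Path to the observation table (CSV/TSV).
#' @param delimiter Field delimiter (default comma).
#' @param normalization `"minmax"` (default) or `"zscore"`.
#' @param training A [training_config()].
#' @param threshold Strength-pruning threshold (default 0.5).
#' @param tie_policy Entropy tie policy, `"drop"` or `"epsilon"`.
#' @param seed Integer seed for the whole run.
#' @param output_dir Directory for `edges.tsv`, `adjacency.csv`, `graph.dot`
#'   and `report.json`.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, delimiter = ",",
                            normalization = c("minmax", "zscore"),
                            training = training_config(),
                            threshold = 0.5,
                            tie_policy = c("drop", "epsilon"),
                            seed = 1L,
                            output_dir = "rlcausal-output") {
  normalization <- match.arg(normalization)
  tie_policy <- match.arg(tie_policy)
  if (threshold < 0) abort("threshold must be >= 0")
  training$seed <- as.integer(seed)
  structure(
    list(
      input = input, delimiter = delimiter, normalization = normalization,
      training = training, threshold = threshold, tie_policy = tie_policy,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Discover a weighted causal structure from a data frame
#'
#' The in-memory core of the pipeline: normalizes the data, runs the
#' actor-critic structure search, annotates the maximum-reward graph with
#' inverse-information-entropy strengths on the normalized data, and prunes
#' edges below the threshold.
#'
#' @param data A data frame or matrix of finite numeric observations.
#' @param training A [training_config()].
#' @param threshold Strength-pruning threshold (default 0.5).
#' @param tie_policy Entropy tie policy (default `"drop"`).
#' @param normalization `"minmax"` (default) or `"zscore"`.
#'
#' @return A list with `graph` (a `weighted_causal_graph`) and `fit`
#'   (the `causal_rl_fit`).
#' @export
causal_discovery <- function(data, training = training_config(),
                             threshold = 0.5,
                             tie_policy = c("drop", "epsilon"),
                             normalization = c("minmax", "zscore")) {
  tie_policy <- match.arg(tie_policy)
  normalization <- match.arg(normalization)
  norm <- normalize_dataset(data, normalization)
  fit <- train_causal_rl(norm, training)
  graph <- annotate_and_prune(norm, fit$best$graph[[1]],
                              threshold = threshold, tie_policy = tie_policy)
  list(graph = graph, fit = fit)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline aborted in stage '%s': %s",
                  stage, conditionMessage(e)),
          class = "rlcausal_pipeline_error", parent = e)
  })
}

#' Run the full pipeline on a file
#'
#' Executes reading, normalization, the reinforcement-learning structure
#' search, strength annotation and pruning, and writes `edges.tsv`,
#' `adjacency.csv`, `graph.dot` and `report.json` to the output directory.
#' Any stage error aborts with the stage name and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with `graph`, `fit`, `report`, `files`.
#' @export
run_pipeline <- function(config) {
  data <- pipeline_stage("read", read_dataset(config$input, config$delimiter))
  norm <- pipeline_stage("normalize",
                         normalize_dataset(data, config$normalization))
  fit <- pipeline_stage("train", train_causal_rl(norm, config$training))
  best_adj <- fit$best$graph[[1]]
  graph <- pipeline_stage("strength", annotate_and_prune(
    norm, best_adj, threshold = config$threshold,
    tie_policy = config$tie_policy
  ))
  report <- list(
    seed = config$seed,
    input = config$input,
    normalization = config$normalization,
    threshold = config$threshold,
    tie_policy = config$tie_policy,
    iterations = config$training$iterations,
    graphs_per_iteration = config$training$graphs_per_iteration,
    learning_rate = config$training$learning_rate,
    critic_hidden = config$training$critic_hidden,
    score_normalization = config$training$score_normalization,
    lambda1 = config$training$reward_config$lambda1,
    lambda2 = config$training$reward_config$lambda2,
    encoder = unclass(config$training$encoder_config),
    variables = fit$variables,
    best_bic = fit$best$bic,
    best_reward = fit$best$reward,
    best_h = fit$best$h,
    best_is_dag = fit$best$is_dag,
    edges_before_pruning = graph$n_edges_before,
    edges_after_pruning = nrow(graph$edges)
  )
  files <- pipeline_stage("write",
                          write_outputs(graph, best_adj, report,
                                        config$output_dir))
  invisible(list(graph = graph, fit = fit, report = report, files = files))
}

#' Write pipeline outputs
#'
#' Writes the weighted edge list (`edges.tsv`, strengths to 6 significant
#' digits), the stage-1 binary adjacency matrix (`adjacency.csv`, header row
#' of variable names), a DOT rendering (`graph.dot`, edges labeled with
#' strength), and the run report (`report.json`). On any I/O failure the
#' files created so far are removed.
#'
#' @param graph A `weighted_causal_graph`.
#' @param adjacency The stage-1 binary adjacency matrix.
#' @param report A named list recorded as `report.json`.
#' @param outdir Output directory (created if missing).
#'
#' @return Invisibly, the named vector of file paths.
#' @export
write_outputs <- function(graph, adjacency, report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    edges = file.path(outdir, "edges.tsv"),
    adjacency = file.path(outdir, "adjacency.csv"),
    dot = file.path(outdir, "graph.dot"),
    report = file.path(outdir, "report.json")
  )
  tryCatch({
    edge_lines <- c(
      "source\ttarget\tstrength",
      sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$to,
              formatC(graph$edges$strength, format = "g", digits = 6))
    )
    writeLines(edge_lines, files[["edges"]])
    utils::write.table(
      adjacency, files[["adjacency"]],
      sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE
    )
    writeLines(render_dot(graph), files[["dot"]])
    jsonlite::write_json(report, files[["report"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(files[file.exists(files)])
    abort(sprintf("failed writing outputs under '%s': %s",
                  outdir, conditionMessage(e)),
          class = "rlcausal_io_error", parent = e)
  })
  invisible(files)
}

render_dot <- function(graph) {
  c(
    "digraph causal {",
    sprintf('  "%s";', graph$variables),
    if (nrow(graph$edges) > 0) {
      sprintf('  "%s" -> "%s" [label="%s"];',
              graph$edges$from, graph$edges$to,
              formatC(graph$edges$strength, format = "g", digits = 6))
    },
    "}"
  )
}
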