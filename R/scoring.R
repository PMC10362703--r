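# Graph scoring: decomposable Gaussian BIC, trace-exponential acyclicity,
# DAG indicator, and the combined reward.

# RSS is clamped below at RSS_FLOOR_PER_ROW * m so that deterministic
# parent-child relationships give a large-but-finite score instead of -Inf;
# the clamp preserves the ranking of all non-degenerate graphs.
RSS_FLOOR_PER_ROW <- 1e-8
ACYCLICITY_TOL <- 1e-8

#' Reward configuration
#'
#' Weights of the two acyclicity penalties in the reward
#' `-(S_BIC + lambda1 * I(not DAG) + lambda2 * h(A))`. The defaults are
#' scaled for a BIC that has been affinely normalized to \[-1, 0\] (the
#' trainer's default); with raw BIC values, larger weights are appropriate.
#'
#' @param lambda1 Nonnegative weight of the DAG-indicator penalty (default 1).
#' @param lambda2 Nonnegative weight of the `h(A)` penalty (default 10).
#'
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(lambda1 = 1, lambda2 = 10) {
  if (lambda1 < 0 || lambda2 < 0) abort("lambda1 and lambda2 must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "reward_config")
}

#' Node-local BIC term
#'
#' Fits one variable on its parent set by least squares with an intercept
#' (Gaussian linear model with per-node residual variance) and returns
#' `m * log(RSS / m) + k * log(m)`, where `k = |parents| + 1` counts the
#' fitted mean parameters. This is the node's contribution to
#' `-2 log-likelihood + d_L log(m)`, dropping the constant
#' `m * (1 + log(2 pi))` that is identical for every node in every graph.
#'
#' @param data A data frame or matrix of observations.
#' @param node Column index of the child variable.
#' @param parents Integer vector of parent column indices (may be empty).
#'
#' @return A single numeric score (lower is better).
#' @export
node_local_bic <- function(data, node, parents = integer(0)) {
  x <- as_dataset_matrix(data)
  parents <- as.integer(parents)
  if (node %in% parents) abort("a node cannot be its own parent")
  if (anyDuplicated(parents)) abort("duplicate parent columns: singular design")
  m <- nrow(x)
  y <- x[, node]
  X <- cbind(1, x[, parents, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    abort("singular design: collinear parent columns",
          class = "rlcausal_fit_error")
  }
  rss <- max(sum(fit$residuals^2), RSS_FLOOR_PER_ROW * m)
  k <- length(parents) + 1
  m * log(rss / m) + k * log(m)
}

graph_parents <- function(graph, node) which(graph[, node] == 1)

check_adjacency <- function(graph) {
  if (!is.matrix(graph) || nrow(graph) != ncol(graph)) {
    abort("adjacency matrix must be square")
  }
  if (!all(graph %in% c(0, 1))) abort("adjacency matrix must be binary")
  if (any(diag(graph) != 0)) abort("adjacency matrix must have a zero diagonal")
  invisible(graph)
}

#' BIC score of a directed graph
#'
#' The Bayesian information criterion of a candidate graph, computed as the
#' sum over nodes of [node_local_bic()] with each node's parents read off the
#' adjacency matrix (entry `(i, j) = 1` means an edge `i -> j`). The score is
#' decomposable, so an optional per-run cache keyed by (node, parent set)
#' avoids refitting repeated families.
#'
#' @param data A data frame or matrix of observations.
#' @param graph A binary `d x d` adjacency matrix with zero diagonal.
#' @param cache Optional environment used as a (node, parent-set) score cache.
#'
#' @return A single numeric score (lower is better).
#' @export
bic_score <- function(data, graph, cache = NULL) {
  check_adjacency(graph)
  d <- ncol(graph)
  total <- 0
  for (j in seq_len(d)) {
    pa <- graph_parents(graph, j)
    if (!is.null(cache)) {
      key <- paste0(j, "|", paste(pa, collapse = ","))
      if (is.null(cache[[key]])) cache[[key]] <- node_local_bic(data, j, pa)
      total <- total + cache[[key]]
    } else {
      total <- total + node_local_bic(data, j, pa)
    }
  }
  total
}

#' Acyclicity function h(A)
#'
#' `h(A) = trace(exp(A)) - d` for a binary adjacency matrix `A`. The matrix
#' exponential is computed by scaling-and-squaring; `h(A)` is exactly zero
#' (within `1e-8`) if and only if the graph is acyclic, because every closed
#' walk contributes positively to the trace of `exp(A)`.
#'
#' @param graph A binary `d x d` adjacency matrix.
#'
#' @return A nonnegative number; 0 for DAGs.
#' @export
acyclicity <- function(graph) {
  h <- sum(diag(pracma::expm(graph))) - ncol(graph)
  max(h, 0)
}

#' Test whether a directed graph is acyclic
#'
#' Kahn-style elimination: repeatedly remove nodes with no incoming edges;
#' the graph is a DAG iff every node can be removed (a topological order
#' exists).
#'
#' @param graph A binary `d x d` adjacency matrix.
#'
#' @return `TRUE` iff the graph is a DAG.
#' @export
is_dag <- function(graph) {
  check_adjacency(graph)
  A <- graph
  alive <- rep(TRUE, ncol(A))
  repeat {
    indeg <- colSums(A[alive, alive, drop = FALSE])
    src <- which(indeg == 0)
    if (length(src) == 0) break
    alive[which(alive)[src]] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  FALSE
}

#' Score a graph and compose the reward
#'
#' Combines the BIC score, the DAG-indicator penalty and the acyclicity
#' penalty into `reward = -(bic + lambda1 * I(not DAG) + lambda2 * h(A))`.
#' For a DAG both penalties vanish and the reward is exactly `-bic`.
#'
#' @param data A data frame or matrix of observations.
#' @param graph A binary `d x d` adjacency matrix with zero diagonal.
#' @param config A [reward_config()].
#' @param cache Optional environment, see [bic_score()].
#'
#' @return A one-row tibble with columns `bic`, `h`, `is_dag`, `reward`, and
#'   a list-column `graph` holding the adjacency matrix.
#' @export
reward <- function(data, graph, config = reward_config(), cache = NULL) {
  bic <- bic_score(data, graph, cache = cache)
  h <- acyclicity(graph)
  dag <- is_dag(graph)
  r <- -(bic + config$lambda1 * (!dag) + config$lambda2 * h)
  tibble::tibble(
    bic = bic, h = h, is_dag = dag, reward = r, graph = list(graph)
  )
}
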