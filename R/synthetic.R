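# Linear structural-equation benchmark: ground-truth DAGs, simulated
# observations, and structural Hamming distance for evaluation.

#' Random directed acyclic graph
#'
#' Samples a strictly upper-triangular binary matrix entrywise
#' Bernoulli(`edge_prob`) and conjugates it by a random node permutation;
#' the result is acyclic by construction.
#'
#' @param d Node count, `2 <= d <= 50`.
#' @param edge_prob Edge probability in \[0, 1\].
#'
#' @return A binary `d x d` adjacency matrix with zero diagonal (columns
#'   named `X1..Xd`).
#' @export
random_dag <- function(d, edge_prob = 0.4) {
  if (d < 2 || d > 50) abort("d must be in [2, 50]")
  if (edge_prob < 0 || edge_prob > 1) abort("edge_prob must be in [0, 1]")
  A <- matrix(0, d, d)
  upper <- upper.tri(A)
  A[upper] <- rbinom(sum(upper), 1L, edge_prob)
  perm <- sample.int(d)
  A <- A[perm, perm]
  dimnames(A) <- list(paste0("X", seq_len(d)), paste0("X", seq_len(d)))
  A
}

#' Random linear structural equation model
#'
#' Attaches edge weights and noise scales to a DAG: weights are drawn from
#' `+/- Uniform[0.5, 2]` by default (bounded away from zero so structures
#' are identifiable in practice), noise is Gaussian with a common scale.
#'
#' @param dag A binary acyclic adjacency matrix, e.g. from [random_dag()].
#' @param weight_range Magnitude range of the uniform weight draw
#'   (default `c(0.5, 2)`); the sign is a fair coin.
#' @param noise_scale Standard deviation of each node's additive Gaussian
#'   noise (default 1).
#'
#' @return An object of class `ground_truth_sem`: list with `dag`, `weights`
#'   (`d x d`, zero off the edge set), `noise_scale`.
#' @export
ground_truth_sem <- function(dag, weight_range = c(0.5, 2), noise_scale = 1) {
  check_adjacency(dag)
  if (!is_dag(dag)) abort("weights require an acyclic graph")
  n_edges <- sum(dag)
  W <- dag * 0
  if (n_edges > 0) {
    mag <- runif(n_edges, weight_range[1], weight_range[2])
    sgn <- sample(c(-1, 1), n_edges, replace = TRUE)
    W[dag == 1] <- mag * sgn
  }
  structure(
    list(dag = dag, weights = W,
         noise_scale = rep_len(noise_scale, ncol(dag))),
    class = "ground_truth_sem"
  )
}

#' Simulate observations from a linear SEM
#'
#' Generates `m` rows by visiting nodes in topological order: each node is
#' the weighted sum of its parents plus independent Gaussian noise.
#'
#' @param sem A [ground_truth_sem()].
#' @param m Number of observations, `m >= 2`.
#'
#' @return A tibble with `m` rows and the DAG's variables as columns.
#' @export
sample_linear_sem <- function(sem, m) {
  if (m < 2) abort("m must be >= 2")
  A <- sem$dag
  if (!is_dag(A)) abort("SEM graph must be acyclic")
  d <- ncol(A)
  ord <- topological_order(A)
  x <- matrix(0, m, d, dimnames = list(NULL, colnames(A)))
  for (j in ord) {
    pa <- graph_parents(A, j)
    mu <- if (length(pa) > 0) {
      x[, pa, drop = FALSE] %*% sem$weights[pa, j]
    } else {
      0
    }
    x[, j] <- mu + rnorm(m, 0, sem$noise_scale[j])
  }
  tibble::as_tibble(as.data.frame(x))
}

topological_order <- function(A) {
  d <- ncol(A)
  alive <- rep(TRUE, d)
  ord <- integer(0)
  while (any(alive)) {
    indeg <- colSums(A[alive, , drop = FALSE])
    src <- which(alive & indeg == 0)
    if (length(src) == 0) abort("graph has a cycle: no topological order")
    ord <- c(ord, src)
    alive[src] <- FALSE
  }
  ord
}

#' Structural Hamming distance
#'
#' Number of edge insertions, deletions and reversals needed to transform
#' one directed graph into another. A reversed edge counts as a single
#' error (the mild convention for orientation mistakes), so SHD is the
#' number of mismatched skeleton entries plus the number of wrongly oriented
#' shared edges.
#'
#' @param truth,estimate Binary adjacency matrices of the same dimension.
#'
#' @return A nonnegative integer.
#' @export
shd <- function(truth, estimate) {
  check_adjacency(truth)
  check_adjacency(estimate)
  if (!all(dim(truth) == dim(estimate))) abort("graphs differ in dimension")
  ## per unordered pair, the status (none / i->j / j->i / both) either
  ## matches or counts one error, so a reversal costs 1, not 2
  status_t <- truth + 2 * t(truth)
  status_e <- estimate + 2 * t(estimate)
  upper <- upper.tri(truth)
  as.integer(sum(status_t[upper] != status_e[upper]))
}
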