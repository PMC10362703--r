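# Stage 2: spacing (Vasicek-type) differential-entropy estimation, inverse
# information entropy (IIE) causal strength, and pruning of weak edges.

STRENGTH_CAP <- 1e12
ENTROPY_DIFF_FLOOR <- 1e-12

#' Spacing estimator of differential entropy
#'
#' Order-statistics estimator of the differential entropy of a continuous
#' variable from an i.i.d. sample: sort ascending and return
#' `psi(n) - psi(1) + mean(log(adjacent spacings))` in nats, where `psi` is
#' the digamma function. The estimator is affine-equivariant:
#' `S(aX + b) = S(X) + log|a|`.
#'
#' Repeated values give zero spacings, on which the estimator is undefined.
#' `tie_policy = "drop"` (default) removes zero spacings from the sum and
#' averages over the remaining count; `"epsilon"` floors every spacing at
#' `1e-12`, which pulls the estimate strongly downward when ties are common.
#'
#' @param x Numeric vector, `n >= 2`, at least two distinct values.
#' @param tie_policy `"drop"` or `"epsilon"`.
#'
#' @return A one-row tibble: `value` (nats), `n`, `zero_spacings`.
#' @export
#'
#' @examples
#' spacing_entropy(c(0, 1))   # exactly 1: psi(2) - psi(1) + log(1)
spacing_entropy <- function(x, tie_policy = c("drop", "epsilon")) {
  tie_policy <- match.arg(tie_policy)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) abort("spacing entropy needs at least 2 observations")
  if (!all(is.finite(x))) abort("entropy input must be finite")
  sp <- diff(sort(x))
  zero <- sum(sp == 0)
  if (zero == n - 1) {
    abort("all values identical: entropy undefined (no information)",
          class = "rlcausal_constant_column_error")
  }
  logsum <- switch(tie_policy,
    drop = sum(log(sp[sp > 0])) / (n - 1 - zero),
    epsilon = sum(log(pmax(sp, 1e-12))) / (n - 1)
  )
  tibble::tibble(
    value = digamma(n) - digamma(1) + logsum,
    n = n,
    zero_spacings = zero
  )
}

#' Inverse-information-entropy causal strength
#'
#' The IIE strength of a (putative) causal relation between two variables:
#' the reciprocal of the absolute difference of their estimated differential
#' entropies, `T = 1 / |S(b) - S(a)|`. Symmetric in its arguments — the
#' statistic weighs an edge but cannot orient it. Pass raw columns for the
#' raw-data strength or normalized columns for the normalized strength; when
#' the entropies coincide (difference below `1e-12`) the result is capped at
#' `1e12` rather than diverging.
#'
#' @param a,b Numeric vectors of equal standing (each a variable's sample).
#' @param tie_policy Passed to [spacing_entropy()].
#'
#' @return A single positive number.
#' @export
iie_strength <- function(a, b, tie_policy = c("drop", "epsilon")) {
  tie_policy <- match.arg(tie_policy)
  sa <- spacing_entropy(a, tie_policy)$value
  sb <- spacing_entropy(b, tie_policy)$value
  gap <- abs(sb - sa)
  if (gap < ENTROPY_DIFF_FLOOR) STRENGTH_CAP else min(1 / gap, STRENGTH_CAP)
}

#' Annotate a discovered graph with causal strengths and prune weak edges
#'
#' Computes the IIE strength of every edge of the stage-1 graph from the
#' supplied (normalized) data and removes edges with strength strictly below
#' the threshold; an edge exactly at the threshold is kept.
#'
#' @param data The data the graph was discovered on (normalized for the
#'   normalized strength).
#' @param graph A binary `d x d` adjacency matrix with zero diagonal.
#' @param threshold Minimum retained strength (default 0.5).
#' @param tie_policy Passed to [spacing_entropy()].
#'
#' @return An object of class `weighted_causal_graph`: list with `edges`
#'   (tibble `from`, `to`, `strength`, sorted by variable order), `variables`,
#'   `threshold`, and `n_edges_before`.
#' @export
annotate_and_prune <- function(data, graph, threshold = 0.5,
                               tie_policy = c("drop", "epsilon")) {
  tie_policy <- match.arg(tie_policy)
  x <- as_dataset_matrix(data)
  check_adjacency(graph)
  if (ncol(graph) != ncol(x)) abort("graph and data dimensions disagree")
  if (threshold < 0) abort("threshold must be >= 0")
  vars <- colnames(x)
  ent <- vapply(seq_len(ncol(x)), function(j) {
    spacing_entropy(x[, j], tie_policy)$value
  }, numeric(1))
  idx <- which(graph == 1, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = vars[idx[, 1]],
    to = vars[idx[, 2]],
    strength = vapply(seq_len(nrow(idx)), function(k) {
      gap <- abs(ent[idx[k, 2]] - ent[idx[k, 1]])
      if (gap < ENTROPY_DIFF_FLOOR) STRENGTH_CAP else min(1 / gap, STRENGTH_CAP)
    }, numeric(1))
  )
  edges <- dplyr::arrange(edges, match(.data$from, vars), match(.data$to, vars))
  kept <- dplyr::filter(edges, .data$strength >= threshold)
  structure(
    list(
      edges = kept,
      variables = vars,
      threshold = threshold,
      tie_policy = tie_policy,
      n_edges_before = nrow(edges)
    ),
    class = "weighted_causal_graph"
  )
}

#' @export
print.weighted_causal_graph <- function(x, ...) {
  cat("<weighted_causal_graph>\n")
  cat(sprintf("  %d variable(s); %d edge(s) kept of %d (threshold %.3g)\n",
              length(x$variables), nrow(x$edges), x$n_edges_before,
              x$threshold))
  if (nrow(x$edges) > 0) {
    print(x$edges, n = 20)
  }
  invisible(x)
}

# Rebuild the binary adjacency matrix of a weighted graph's kept edges.
wcg_adjacency <- function(wcg) {
  d <- length(wcg$variables)
  A <- matrix(0, d, d, dimnames = list(wcg$variables, wcg$variables))
  if (nrow(wcg$edges) > 0) {
    A[cbind(match(wcg$edges$from, wcg$variables),
            match(wcg$edges$to, wcg$variables))] <- 1
  }
  A
}
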