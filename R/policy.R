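# Graph-generating policy: variable embedding, stacked self-attention encoder,
# pairwise single-layer decoder, and Bernoulli adjacency sampling.

#' Encoder configuration
#'
#' Hyperparameters of the self-attention encoder that turns the d variables of
#' an observation table into d summary vectors. The full-size defaults are six
#' encoding layers of width 512 with 8 heads and a 4x feedforward expansion;
#' tests and small problems run a reduced network (e.g. `n_layers = 2`,
#' `d_model = 16`).
#'
#' @param n_layers Number of identical encoding layers (default 6).
#' @param d_model Shared width of embeddings and all sublayer outputs
#'   (default 512).
#' @param n_heads Attention heads; must divide `d_model` (default 8).
#' @param d_ff Hidden width of the position-wise feedforward sublayer
#'   (default `4 * d_model`).
#' @param n_s Number of observation rows sampled to represent each variable
#'   (default 64).
#'
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 6L, d_model = 512L, n_heads = 8L,
                           d_ff = 4L * d_model, n_s = 64L) {
  cfg <- list(
    n_layers = as.integer(n_layers), d_model = as.integer(d_model),
    n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
    n_s = as.integer(n_s)
  )
  if (any(unlist(cfg) < 1L)) abort("all encoder_config fields must be >= 1")
  if (cfg$d_model %% cfg$n_heads != 0L) {
    abort("d_model must be divisible by n_heads")
  }
  structure(cfg, class = "encoder_config")
}

#' Initialize policy-network parameters
#'
#' Creates the trainable parameters of the graph-generating policy: a linear
#' variable-embedding map (`n_s` sampled values to `d_model`), `n_layers`
#' encoder layers, and the pairwise decoder `u' tanh(W1 enc_i + W2 enc_j)`.
#' Weights are Glorot-uniform draws from the current RNG stream.
#'
#' @param cfg An [encoder_config()].
#' @param d_h Hidden width of the decoder (default `d_model`).
#'
#' @return A list of class `rl_policy` with elements `cfg` and `params`.
#' @export
init_policy <- function(cfg = encoder_config(), d_h = cfg$d_model) {
  params <- list(
    emb = list(W = glorot(cfg$n_s, cfg$d_model), b = numeric(cfg$d_model)),
    layers = lapply(seq_len(cfg$n_layers), function(i) {
      init_encoder_layer(cfg$d_model, cfg$d_ff)
    }),
    dec = list(
      W1 = glorot(d_h, cfg$d_model),
      W2 = glorot(d_h, cfg$d_model),
      u = glorot(d_h, 1)[, 1]
    )
  )
  structure(list(cfg = cfg, params = params, d_h = as.integer(d_h)),
            class = "rl_policy")
}

#' Embed variables from sampled observation rows
#'
#' Draws `n_s` observation rows uniformly without replacement and represents
#' each variable by its `n_s` sampled values passed through the policy's
#' shared linear map to width `d_model`. Variables carry no positional
#' encoding: they are an unordered set, and the encoder downstream is
#' permutation-equivariant.
#'
#' @param data A data frame or matrix of finite numeric observations.
#' @param policy An [init_policy()] object.
#'
#' @return A `d x d_model` embedding matrix (rows named by variable).
#' @export
embed_variables <- function(data, policy) {
  x <- as_dataset_matrix(data)
  n_s <- policy$cfg$n_s
  if (n_s > nrow(x)) {
    abort(sprintf("n_s = %d exceeds the %d available rows", n_s, nrow(x)),
          class = "rlcausal_sampling_error")
  }
  rows <- sample.int(nrow(x), n_s)
  S <- t(x[rows, , drop = FALSE])          # d x n_s: variable j -> its samples
  emb <- sweep(S %*% policy$params$emb$W, 2, policy$params$emb$b, `+`)
  rownames(emb) <- colnames(x)
  attr(emb, "sample_matrix") <- S          # kept for backpropagation
  emb
}

#' Encode embedded variables with stacked self-attention
#'
#' Applies `n_layers` identical encoding layers. Each layer is a multi-head
#' self-attention sublayer followed by a position-wise feedforward sublayer,
#' both wrapped as `LayerNorm(x + Sublayer(x))`. All sublayer outputs share
#' the embedding width, so the encoder output is `d x d_model`.
#'
#' @param emb A `d x d_model` embedding matrix from [embed_variables()].
#' @param policy An [init_policy()] object.
#' @param keep_cache Keep intermediate activations for backpropagation
#'   (internal; default `FALSE`).
#'
#' @return A `d x d_model` matrix of encoder outputs, one row per variable.
#' @export
encode <- function(emb, policy, keep_cache = FALSE) {
  x <- emb
  caches <- if (keep_cache) vector("list", policy$cfg$n_layers)
  for (l in seq_len(policy$cfg$n_layers)) {
    out <- encoder_layer_forward(x, policy$params$layers[[l]], policy$cfg$n_heads)
    x <- out$y
    if (keep_cache) caches[[l]] <- out$cache
  }
  if (!all(is.finite(x))) abort("non-finite encoder activations")
  rownames(x) <- rownames(emb)
  if (keep_cache) attr(x, "cache") <- caches
  x
}

# Backpropagate d(loss)/d(enc) through the encoder layers and the embedding
# map. Returns a gradient tree matching policy$params.
encoder_backward <- function(denc, enc, emb, policy) {
  caches <- attr(enc, "cache")
  layer_grads <- vector("list", policy$cfg$n_layers)
  dx <- denc
  for (l in rev(seq_len(policy$cfg$n_layers))) {
    bk <- encoder_layer_backward(dx, policy$params$layers[[l]], caches[[l]])
    dx <- bk$dx
    layer_grads[[l]] <- bk$grads
  }
  S <- attr(emb, "sample_matrix")
  list(
    emb = list(W = t(S) %*% dx, b = colSums(dx)),
    layers = layer_grads
  )
}

#' Pairwise edge logits from encoder outputs
#'
#' Cycles over all ordered variable pairs (i, j) and computes the decoder
#' score `u' tanh(W1 enc_i + W2 enc_j)`, the logit of the probability of an
#' edge i -> j. Diagonal entries are computed but masked: graph sampling
#' never consults them (no self-loops).
#'
#' @param enc A `d x d_n` matrix of encoder outputs.
#' @param policy An [init_policy()] object (supplies `W1`, `W2`, `u`).
#' @param keep_cache Keep the tanh activations for backpropagation (internal).
#'
#' @return A `d x d` numeric logit matrix with attribute `masked_diagonal`.
#' @export
edge_logits <- function(enc, policy, keep_cache = FALSE) {
  dec <- policy$params$dec
  d <- nrow(enc)
  A1 <- enc %*% t(dec$W1)                  # d x d_h
  A2 <- enc %*% t(dec$W2)
  d_h <- ncol(A1)
  g <- matrix(0, d, d)
  tanh_cache <- if (keep_cache) array(0, c(d, d, d_h))
  for (h in seq_len(d_h)) {
    Th <- tanh(outer(A1[, h], A2[, h], `+`))
    g <- g + dec$u[h] * Th
    if (keep_cache) tanh_cache[, , h] <- Th
  }
  dimnames(g) <- list(rownames(enc), rownames(enc))
  attr(g, "masked_diagonal") <- TRUE
  if (keep_cache) attr(g, "tanh_cache") <- tanh_cache
  g
}

# Backpropagate d(loss)/d(logits) to decoder parameters and encoder outputs.
decoder_backward <- function(dg, logits, enc, policy) {
  dec <- policy$params$dec
  Th <- attr(logits, "tanh_cache")
  d_h <- length(dec$u)
  d <- nrow(enc)
  du <- numeric(d_h)
  dA1 <- matrix(0, d, d_h)
  dA2 <- matrix(0, d, d_h)
  for (h in seq_len(d_h)) {
    T_h <- Th[, , h]
    du[h] <- sum(dg * T_h)
    dpre <- dg * dec$u[h] * (1 - T_h^2)
    dA1[, h] <- rowSums(dpre)
    dA2[, h] <- colSums(dpre)
  }
  list(
    grads = list(
      W1 = t(dA1) %*% enc,
      W2 = t(dA2) %*% enc,
      u = du
    ),
    denc = dA1 %*% dec$W1 + dA2 %*% dec$W2
  )
}

#' Sample a directed graph from edge logits
#'
#' Each off-diagonal entry of the adjacency matrix is drawn independently as
#' Bernoulli with probability `sigma(logit)`. The diagonal is forced to zero
#' to rule out self-loops. The returned log-probability is the sum of the
#' edgewise Bernoulli log-masses of the realized off-diagonal entries.
#'
#' @param logits A `d x d` logit matrix (finite off-diagonal).
#' @param n Number of independent graphs to draw (default 1).
#'
#' @return For `n = 1`, a list with `adjacency` (binary `d x d`, zero
#'   diagonal) and `log_prob`; for `n > 1`, a list of such lists.
#' @export
sample_graph <- function(logits, n = 1L) {
  d <- nrow(logits)
  off <- row(logits) != col(logits)
  if (!all(is.finite(logits[off]))) abort("off-diagonal logits must be finite")
  p <- 1 / (1 + exp(-logits))
  draws <- lapply(seq_len(n), function(k) {
    A <- matrix(0, d, d, dimnames = dimnames(logits))
    A[off] <- rbinom(sum(off), 1L, p[off])
    lp <- sum(ifelse(A[off] == 1, log(p[off]), log1p(-p[off])))
    list(adjacency = A, log_prob = lp)
  })
  if (n == 1L) draws[[1]] else draws
}
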