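# Shared fixtures: small networks and simulated structural-equation data.

small_encoder <- function(n_s = 64L) {
  encoder_config(n_layers = 2L, d_model = 16L, n_heads = 4L, d_ff = 64L,
                 n_s = n_s)
}

small_training <- function(seed, iterations, graphs_per_iteration = 32L,
                           n_s = 64L, ...) {
  training_config(
    iterations = iterations, graphs_per_iteration = graphs_per_iteration,
    seed = seed, encoder_config = small_encoder(n_s), critic_hidden = 16L, ...
  )
}

# X1 -> X2 -> X3 chain with strong linear effects, min-max normalized.
chain3_data <- function(m = 500, seed = 11) {
  set.seed(seed)
  x1 <- rnorm(m)
  x2 <- 1.5 * x1 + rnorm(m)
  x3 <- -1.2 * x2 + rnorm(m)
  normalize_dataset(data.frame(X1 = x1, X2 = x2, X3 = x3))
}

# The seeded d = 5 benchmark instance: random DAG (edge prob 0.4), weights
# +/- U[0.5, 2], unit Gaussian noise, m rows.
bench5 <- function(m = 1000, seed = 1) {
  set.seed(seed)
  dag <- random_dag(5, 0.4)
  sem <- ground_truth_sem(dag)
  list(dag = dag, sem = sem, data = sample_linear_sem(sem, m))
}

# Every d-node binary digraph with zero diagonal, as a list (2^(d(d-1))).
all_digraphs <- function(d) {
  off <- which(diag(d) == 0)
  n_off <- length(off)
  lapply(0:(2^n_off - 1), function(mask) {
    A <- matrix(0, d, d)
    A[off] <- bitwAnd(mask, 2^(seq_len(n_off) - 1)) > 0
    A
  })
}

write_csv_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
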