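# Dense neural-network primitives used by the policy network and the critic.
# Everything is plain double matrix algebra: the graphs involved are tiny
# (d <= a few dozen variables), so hand-rolled forward/backward passes and an
# Adam optimizer are both simple and fast on one CPU.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## ---- parameter trees -------------------------------------------------------

# Parameters are nested lists of numeric arrays; these helpers walk two trees
# of identical shape in lock-step.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

zeros_like <- function(a) tree_map(function(x) x * 0, a)

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One Adam update (Kingma & Ba) on a parameter tree; returns updated params
# and state. `direction = -1` descends the gradient (minimization).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- tree_map2(
    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
    state$m, state$v
  )
  params <- tree_map2(`-`, params, step)
  list(params = params, state = state)
}

## ---- layer normalization ---------------------------------------------------

LN_EPS <- 1e-6

layernorm_forward <- function(x, gain, bias) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + LN_EPS)
  xhat <- xc / sd
  y <- sweep(xhat, 2, gain, `*`)
  y <- sweep(y, 2, bias, `+`)
  list(y = y, cache = list(xhat = xhat, sd = sd, gain = gain))
}

layernorm_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$gain, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dgain = colSums(dy * xhat), dbias = colSums(dy))
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

## ---- one encoder layer: self-attention + feedforward, both residual -------

init_encoder_layer <- function(d_model, d_ff) {
  list(
    Wq = glorot(d_model, d_model),
    Wk = glorot(d_model, d_model),
    Wv = glorot(d_model, d_model),
    Wo = glorot(d_model, d_model),
    bo = numeric(d_model),
    g1 = rep(1, d_model), b1 = numeric(d_model),
    Wf1 = glorot(d_model, d_ff), bf1 = numeric(d_ff),
    Wf2 = glorot(d_ff, d_model), bf2 = numeric(d_model),
    g2 = rep(1, d_model), b2 = numeric(d_model)
  )
}

# x: d x d_model. Multi-head self-attention sublayer, then position-wise
# feedforward, each wrapped as LayerNorm(input + sublayer(input)).
encoder_layer_forward <- function(x, p, n_heads) {
  d_model <- ncol(x)
  dk <- d_model %/% n_heads
  Q <- x %*% p$Wq
  K <- x %*% p$Wk
  V <- x %*% p$Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, nrow(x), d_model)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    P <- softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    heads[[h]] <- list(P = P, idx = idx)
  }
  att <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  ln1 <- layernorm_forward(x + att, p$g1, p$b1)
  x1 <- ln1$y
  pre <- sweep(x1 %*% p$Wf1, 2, p$bf1, `+`)
  act <- pmax(pre, 0)
  ff <- sweep(act %*% p$Wf2, 2, p$bf2, `+`)
  ln2 <- layernorm_forward(x1 + ff, p$g2, p$b2)
  list(
    y = ln2$y,
    cache = list(
      x = x, Q = Q, K = K, V = V, O = O, heads = heads,
      ln1 = ln1$cache, x1 = x1, pre = pre, act = act, ln2 = ln2$cache,
      n_heads = n_heads, dk = dk
    )
  )
}

encoder_layer_backward <- function(dy, p, cache) {
  x <- cache$x
  d_model <- ncol(x)
  ## feedforward sublayer
  b2 <- layernorm_backward(dy, cache$ln2)
  dr2 <- b2$dx                       # gradient at x1 + ff
  dff <- dr2
  dWf2 <- t(cache$act) %*% dff
  dbf2 <- colSums(dff)
  dact <- dff %*% t(p$Wf2)
  dpre <- dact * (cache$pre > 0)
  dWf1 <- t(cache$x1) %*% dpre
  dbf1 <- colSums(dpre)
  dx1 <- dr2 + dpre %*% t(p$Wf1)
  ## attention sublayer
  b1 <- layernorm_backward(dx1, cache$ln1)
  dr1 <- b1$dx                       # gradient at x + att
  datt <- dr1
  dWo <- t(cache$O) %*% datt
  dbo <- colSums(datt)
  dO <- datt %*% t(p$Wo)
  dQ <- matrix(0, nrow(x), d_model)
  dK <- matrix(0, nrow(x), d_model)
  dV <- matrix(0, nrow(x), d_model)
  for (h in seq_along(cache$heads)) {
    hd <- cache$heads[[h]]
    idx <- hd$idx
    P <- hd$P
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dP <- dOh %*% t(Vh)
    dV[, idx] <- t(P) %*% dOh
    dS <- P * (dP - rowSums(dP * P))
    dS <- dS / sqrt(cache$dk)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE]
  }
  dWq <- t(x) %*% dQ
  dWk <- t(x) %*% dK
  dWv <- t(x) %*% dV
  dx <- dr1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(
    dx = dx,
    grads = list(
      Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, bo = dbo,
      g1 = b1$dgain, b1 = b1$dbias,
      Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2,
      g2 = b2$dgain, b2 = b2$dbias
    )
  )
}
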