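test_that("spacing entropy matches hand-computable cases", {
  # psi(2) - psi(1) = 1 by the digamma recurrence; log(1) = 0
  expect_equal(spacing_entropy(c(0, 1))$value, 1)
  expect_equal(spacing_entropy(c(0, exp(1)))$value, 2)
  # order must not matter
  expect_equal(spacing_entropy(c(3, 1, 2))$value,
               spacing_entropy(c(1, 2, 3))$value)
})

test_that("spacing entropy approaches closed-form differential entropies", {
  set.seed(41)
  u <- mean(replicate(20, spacing_entropy(runif(5000))$value))
  g <- mean(replicate(20, spacing_entropy(rnorm(5000))$value))
  expect_lt(abs(u - 0), 0.05)
  expect_lt(abs(g - 0.5 * log(2 * pi * exp(1))), 0.05)
})

test_that("spacing entropy is affine-equivariant", {
  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(200, sd = runif(1, 0.5, 3))
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, sd = 5)
    expect_equal(spacing_entropy(a * x + b)$value,
                 spacing_entropy(x)$value + log(a),
                 tolerance = 1e-10)
  }
})

test_that("estimator error shrinks with the sample size", {
  set.seed(43)
  err <- function(n, rdist, truth) {
    mean(abs(replicate(50, spacing_entropy(rdist(n))$value) - truth))
  }
  expect_lt(err(5000, runif, 0), err(100, runif, 0))
  expect_lt(err(5000, rnorm, 0.5 * log(2 * pi * exp(1))),
            err(100, rnorm, 0.5 * log(2 * pi * exp(1))))
})

test_that("tie policies handle repeated values, all-equal input errors", {
  x <- c(0, 0, 0, 1, 2)          # two zero spacings
  est <- spacing_entropy(x)
  expect_identical(est$zero_spacings, 2L)
  # drop: average log spacings over the 2 nonzero gaps
  expect_equal(est$value, digamma(5) - digamma(1) + (log(1) + log(1)) / 2)
  eps <- spacing_entropy(x, tie_policy = "epsilon")
  expect_lt(eps$value, est$value)   # floored spacings drag the sum down
  expect_error(spacing_entropy(rep(3, 10)),
               class = "rlcausal_constant_column_error")
})

test_that("IIE strength is the reciprocal entropy gap, symmetric, capped", {
  set.seed(44)
  a <- runif(500)                       # entropy near 0
  b <- 2 * runif(500)                   # entropy near log 2
  t_ab <- iie_strength(a, b)
  gap <- abs(spacing_entropy(b)$value - spacing_entropy(a)$value)
  expect_equal(t_ab, 1 / gap)
  expect_equal(iie_strength(b, a), t_ab)
  expect_equal(iie_strength(a, a), 1e12)   # identical entropies hit the cap
})

test_that("raw strength moves under column scaling but normalized does not", {
  set.seed(45)
  x <- runif(800)
  y <- rnorm(800)
  raw1 <- iie_strength(x, y)
  raw2 <- iie_strength(5 * x, y)
  expect_false(isTRUE(all.equal(raw1, raw2)))
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_equal(iie_strength(mm(5 * x), mm(y)), iie_strength(mm(x), mm(y)))
})

test_that("pruning removes weak edges, keeps the boundary, stays a subset", {
  set.seed(46)
  # engineer entropies ~0 and ~-1.9: U(0,1) vs a spiky Beta on [0,1]
  u <- runif(2000)
  v <- rbeta(2000, 0.05, 0.05)
  w <- runif(2000, 0, 1)^1.15
  x <- cbind(U = u, V = v, W = w)
  A <- matrix(0, 3, 3, dimnames = list(colnames(x), colnames(x)))
  A[1, 2] <- 1    # U -> V: big entropy gap, weak strength
  A[1, 3] <- 1    # U -> W: tiny gap, strong
  wcg <- annotate_and_prune(x, A)
  expect_s3_class(wcg, "weighted_causal_graph")
  expect_identical(wcg$n_edges_before, 2L)
  expect_true(all(wcg$edges$strength >= 0.5))
  expect_false("V" %in% wcg$edges$to)    # the weak edge was removed
  expect_true(any(wcg$edges$to == "W"))
  # boundary inclusive: a threshold exactly at the kept edge's strength keeps it
  s <- wcg$edges$strength[1]
  at_boundary <- annotate_and_prune(x, A, threshold = s)
  expect_true(s %in% at_boundary$edges$strength)
})

test_that("pruning is monotone in the threshold and never adds edges", {
  set.seed(47)
  x <- matrix(runif(500 * 4)^rep(c(1, 2, 3, 4), each = 500), 500, 4,
              dimnames = list(NULL, paste0("X", 1:4)))
  A <- matrix(1, 4, 4) - diag(4)
  lo <- annotate_and_prune(x, A, threshold = 0.5)
  hi <- annotate_and_prune(x, A, threshold = 2)
  key <- function(w) paste(w$edges$from, w$edges$to)
  expect_true(all(key(hi) %in% key(lo)))
  expect_true(all(key(lo) %in% paste(rep(colnames(x), 4),
                                     rep(colnames(x), each = 4))))
  empty <- annotate_and_prune(x, matrix(0, 4, 4))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(empty$n_edges_before, 0L)
})

test_that("weighted graph tidiers return the edge list and summary", {
  set.seed(48)
  x <- cbind(a = runif(300), b = runif(300, 0, 2))
  A <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  wcg <- annotate_and_prune(x, A)
  expect_named(tidy(wcg), c("from", "to", "strength"))
  gl <- glance(wcg)
  expect_identical(gl$n_variables, 2L)
  expect_identical(gl$threshold, 0.5)
})
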