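test_that("parent-free node score matches the closed-form variance fit", {
  set.seed(21)
  m <- 1000
  y <- rnorm(m)
  x <- cbind(a = y, b = rnorm(m))
  rss <- sum((y - mean(y))^2)
  expect_equal(node_local_bic(x, 1, integer(0)),
               m * log(rss / m) + log(m))
})

test_that("adding a parent never increases the residual sum of squares", {
  set.seed(22)
  x <- cbind(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  m <- 200
  # strip the k log m penalty to compare pure fit terms
  rss_of <- function(parents) {
    k <- length(parents) + 1
    exp((node_local_bic(x, 1, parents) - k * log(m)) / m) * m
  }
  expect_lte(rss_of(2L), rss_of(integer(0)) + 1e-9)
  expect_lte(rss_of(c(2L, 3L)), rss_of(2L) + 1e-9)
})

test_that("deterministic relationships hit the RSS floor, not -Inf", {
  x <- cbind(a = 1:50 + 0, b = 2 * (1:50))
  s <- node_local_bic(x, 2, 1L)
  expect_true(is.finite(s))
  expect_equal(s, 50 * log(1e-8 * 50 / 50) + 2 * log(50))
})

test_that("degenerate designs are rejected", {
  x <- cbind(a = rnorm(30), b = rnorm(30))
  expect_error(node_local_bic(x, 1, 1L), "own parent")
  expect_error(node_local_bic(cbind(x, c = x[, "b"]), 1, c(2L, 3L)),
               class = "rlcausal_fit_error")
})

test_that("the graph score decomposes over node-local terms", {
  set.seed(23)
  x <- matrix(rnorm(150 * 4), 150, 4, dimnames = list(NULL, paste0("X", 1:4)))
  for (rep in 1:20) {
    A <- random_dag(4, 0.5)
    expect_equal(
      bic_score(x, A),
      sum(vapply(1:4, function(j) {
        node_local_bic(x, j, which(A[, j] == 1))
      }, numeric(1)))
    )
  }
})

test_that("a strong linear effect is preferred over the empty graph", {
  set.seed(24)
  m <- 500
  x1 <- rnorm(m)
  x2 <- 2 * x1 + rnorm(m)
  x <- cbind(X1 = x1, X2 = x2)
  edge <- matrix(c(0, 0, 1, 0), 2, 2)   # X1 -> X2
  empty <- matrix(0, 2, 2)
  expect_lt(bic_score(x, edge), bic_score(x, empty))
})

test_that("acyclicity matches closed forms", {
  expect_equal(acyclicity(matrix(0, 3, 3)), 0)
  expect_equal(acyclicity(matrix(c(0, 1, 1, 0), 2, 2)), 2 * cosh(1) - 2,
               tolerance = 1e-6)
  set.seed(25)
  for (rep in 1:20) {
    A <- matrix(0, 4, 4)
    A[upper.tri(A)] <- rbinom(6, 1, 0.6)
    expect_lt(acyclicity(A), 1e-8)   # nilpotent: unit diagonal of exp(A)
  }
})

test_that("h(A) = 0 exactly characterizes DAGs on all 3-node digraphs", {
  for (A in all_digraphs(3)) {
    expect_identical(acyclicity(A) < 1e-8, is_dag(A))
  }
})

test_that("is_dag agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(26)
  for (rep in 1:50) {
    A <- matrix(rbinom(25, 1, 0.3), 5, 5)
    diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    expect_identical(is_dag(A), igraph::is_dag(g))
  }
})

test_that("reward composes BIC and the two penalties exactly", {
  set.seed(27)
  x <- chain3_data(m = 200)
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 1
  rec <- reward(x, chain)
  expect_true(rec$is_dag)
  expect_equal(rec$h, 0)
  expect_equal(rec$reward, -rec$bic)

  two_cycle <- matrix(0, 3, 3)
  two_cycle[1, 2] <- two_cycle[2, 1] <- 1
  rec2 <- reward(x, two_cycle, reward_config(lambda1 = 1, lambda2 = 1))
  expect_false(rec2$is_dag)
  expect_equal(rec2$reward, -(rec2$bic + 1 + (2 * cosh(1) - 2)),
               tolerance = 1e-9)

  # nonincreasing in both penalty weights on a cyclic graph
  r_small <- reward(x, two_cycle, reward_config(1, 1))$reward
  r_big1 <- reward(x, two_cycle, reward_config(5, 1))$reward
  r_big2 <- reward(x, two_cycle, reward_config(1, 5))$reward
  expect_lte(r_big1, r_small)
  expect_lte(r_big2, r_small)
})

test_that("the BIC cache returns the same scores as direct evaluation", {
  set.seed(28)
  x <- matrix(rnorm(100 * 3), 100, 3)
  cache <- new.env()
  for (A in all_digraphs(3)[c(1, 5, 9, 20, 40)]) {
    expect_equal(bic_score(x, A, cache = cache), bic_score(x, A))
  }
})
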