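test_that("critic output is a finite scalar, zero for zero weights", {
  set.seed(31)
  enc <- matrix(rnorm(8 * 16), 8, 16)
  critic <- rlcausal:::init_critic(16, 8)
  expect_length(critic_predict(enc, critic), 1)
  expect_true(is.finite(critic_predict(enc, critic)))
  zero <- rlcausal:::zeros_like(critic)
  expect_equal(critic_predict(enc, zero), 0)
})

test_that("critic prediction is invariant to permuting the encoder rows", {
  set.seed(32)
  enc <- matrix(rnorm(6 * 16), 6, 16)
  critic <- rlcausal:::init_critic(16, 8)
  expect_equal(critic_predict(enc, critic),
               critic_predict(enc[sample(6), ], critic))
})

test_that("a single-iteration single-graph run returns that graph as best", {
  dat <- chain3_data(m = 100)
  fit <- train_causal_rl(dat, small_training(seed = 3, iterations = 1,
                                             graphs_per_iteration = 1))
  expect_identical(nrow(fit$graph_log), 1L)
  expect_identical(fit$best$graph[[1]], fit$graph_log$graph[[1]])
  expect_equal(fit$best$reward, fit$graph_log$reward)
})

test_that("best-so-far reward trace is nondecreasing and best is the log max", {
  dat <- chain3_data(m = 200)
  fit <- train_causal_rl(dat, small_training(seed = 4, iterations = 30))
  expect_true(all(diff(fit$trace$best_reward) >= 0))
  expect_equal(fit$best$reward, max(fit$graph_log$reward))
  expect_identical(nrow(fit$trace), 30L)
})

test_that("seeded runs reproduce the identical best graph", {
  dat <- chain3_data(m = 200)
  f1 <- train_causal_rl(dat, small_training(seed = 5, iterations = 20))
  f2 <- train_causal_rl(dat, small_training(seed = 5, iterations = 20))
  expect_identical(f1$best$graph[[1]], f2$best$graph[[1]])
  expect_equal(f1$best$bic, f2$best$bic)
  expect_equal(f1$trace, f2$trace)
})

test_that("large acyclicity penalties force a DAG as the best graph", {
  dat <- chain3_data(m = 200)
  for (s in 1:3) {
    fit <- train_causal_rl(dat, small_training(
      seed = s, iterations = 200,
      reward_config = reward_config(lambda1 = 1e3, lambda2 = 1e3)
    ))
    expect_true(fit$best$is_dag)
    expect_equal(fit$best$h, 0)
  }
})

test_that("the training log records one JSON line per iteration", {
  dat <- chain3_data(m = 100)
  log <- withr::local_tempfile(fileext = ".jsonl")
  fit <- train_causal_rl(dat, small_training(seed = 6, iterations = 5,
                                             log_file = log))
  lines <- readLines(log)
  expect_length(lines, 5)
  rec <- jsonlite::fromJSON(lines[3])
  expect_named(rec, c("iteration", "mean_reward", "best_bic_so_far",
                      "h_best_batch"))
  expect_identical(rec$iteration, 3L)
})

test_that("exhaustive search enumerates all DAGs and returns the optimum", {
  dat <- chain3_data(m = 500)
  res <- exhaustive_search(dat)
  expect_identical(res$n_dags, 25)
  expect_true(res$is_dag)
  expect_equal(res$h, 0)
  # independent brute-force oracle over all 64 three-node digraphs
  dags <- Filter(is_dag, all_digraphs(3))
  expect_length(dags, 25)
  brute <- min(vapply(dags, function(A) bic_score(dat, A), numeric(1)))
  expect_equal(res$bic, brute)
  # the chain's equivalence class should win on chain data
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 1
  expect_equal(res$bic, bic_score(dat, chain), tolerance = 1e-6)
})

test_that("exhaustive search on independent columns returns the empty graph", {
  set.seed(33)
  x <- cbind(X1 = rnorm(400), X2 = rnorm(400))
  res <- exhaustive_search(x)
  expect_identical(res$n_dags, 3)
  expect_equal(sum(res$graph[[1]]), 0)
})

test_that("exhaustive search refuses more than 5 variables", {
  set.seed(34)
  x <- matrix(rnorm(60), 10, 6)
  expect_error(exhaustive_search(x), "explodes")
})

test_that("tidy and glance expose the fit the broom way", {
  dat <- chain3_data(m = 100)
  fit <- train_causal_rl(dat, small_training(seed = 7, iterations = 10))
  tr <- tidy(fit)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("iteration", "best_reward", "mean_reward"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$iterations, 10L)
  expect_identical(gl$graphs_scored, nrow(tidy(fit, "graphs")))
})
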