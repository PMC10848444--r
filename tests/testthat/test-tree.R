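# Single rank-based trees: impurity, split statistic, pair search, growth,
# routing.

test_that("gini impurity matches its closed form and validates input", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(0.3, 0.7)), 0.42)
  expect_error(gini_impurity(c(-0.1, 1.1)),
               class = "pairtree_proportion_error")
  expect_error(gini_impurity(c(0.4, 0.4)),
               class = "pairtree_proportion_error")
})

test_that("split statistic g equals one minus weighted daughter Gini", {
  expect_equal(split_statistic_g(c(2, 0), c(2, 2)), 1.0)
  expect_equal(split_statistic_g(c(2, 2), c(4, 4)), 0.5)
  expect_error(split_statistic_g(c(0, 0), c(2, 2)),
               class = "pairtree_count_error")
  set.seed(99)
  for (r in 1:300) {
    K <- sample(2:5, 1)
    total <- rpois(K, 6) + 1L
    repeat {
      left <- vapply(total, function(t) sample.int(t + 1L, 1L) - 1L, 0L)
      if (sum(left) > 0 && sum(left) < sum(total)) break
    }
    g <- split_statistic_g(left, total)
    expect_equal(g, 1 - oracle_weighted_gini(left, total),
                 tolerance = 1e-12)
  }
})

test_that("node-level pair search agrees with exhaustive brute force", {
  set.seed(5)
  for (r in 1:30) {
    n <- sample(6:30, 1); P <- sample(3:8, 1); K <- sample(2:3, 1)
    X <- matrix(runif(n * P), n, P)
    y <- sample.int(K, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 1:2
    idx <- seq_len(n)
    got <- pairtree:::.best_pair_split(X, y, max(y), idx, seq_len(P))
    want <- oracle_best_pair(X, y, idx, seq_len(P))
    if (is.null(want)) expect_null(got)
    else expect_equal(unname(got), unname(want))
  }
})

test_that("pure or unsplittable nodes yield no split", {
  X <- matrix(runif(20), 10, 2)
  expect_null(pairtree:::.best_pair_split(X, rep(1L, 10), 2L, 1:10, 1:2))
  # identical indicator for the single candidate pair everywhere
  X2 <- cbind(1:10, 11:20)
  y <- rep(1:2, 5)
  expect_null(pairtree:::.best_pair_split(X2, y, 2L, 1:10, 1:2))
})

test_that("a depth-1 tree is a top-scoring-pair classifier", {
  d <- tiny_pair_data(n = 40, P = 5, seed = 2)
  fit <- rank_tree(d$X, d$y, max_depth = 1, seed = 1)
  expect_equal(max(fit$tree$depth), 1L)
  expect_equal(sort(c(fit$tree$var_i[1], fit$tree$var_j[1])), c(1L, 2L))
  expect_equal(mean(predict(fit, d$X) == d$y), 1.0)
})

test_that("an unrestricted tree memorises tie-free separable data", {
  sim <- simulate_rank_data(n_samples = 60, n_genes = 12, n_pairs = 3,
                            flip_noise = 0, seed = 8)
  fit <- rank_tree(sim$data, seed = 3)   # default: exhaustive pair search
  expect_equal(mean(predict(fit, sim$data) == sim$data$labels), 1.0)
  # terminal counts partition the training samples
  term <- fit$tree$var_i == 0L
  expect_equal(sum(fit$tree$counts[term, ]), 60)
})

test_that("pure training labels give a depth-0 tree", {
  X <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  tr <- pairtree:::.grow_tree(X, yint = rep(1L, 10), K = 2L, idx = 1:10,
                              n_candidate_genes = 2)
  expect_length(tr$var_i, 1L)
  expect_equal(tr$var_i, 0L)
})

test_that("regression trees split by sum-of-squares reduction", {
  # constant response: no split, node value is that constant
  X <- matrix(runif(40), 20, 2)
  tr <- pairtree:::.grow_tree(X, z = rep(2.5, 20), idx = 1:20,
                              n_candidate_genes = 2)
  expect_equal(tr$var_i, 0L)
  expect_equal(tr$value, 2.5)

  # z = +-1 by the pair order: one split on (1, 2), node means +1 / -1
  d <- tiny_pair_data(n = 30, P = 4, seed = 4)
  z <- ifelse(d$X[, 1] < d$X[, 2], 1, -1)
  tr <- pairtree:::.grow_tree(d$X, z = z, idx = 1:30, max_depth = 1,
                              n_candidate_genes = 4)
  expect_equal(sort(c(tr$var_i[1], tr$var_j[1])), c(1L, 2L))
  left_val <- tr$value[tr$left[1]]
  right_val <- tr$value[tr$right[1]]
  if (tr$var_i[1] == 1L) expect_equal(c(left_val, right_val), c(1, -1))
  else expect_equal(c(left_val, right_val), c(-1, 1))

  # the chosen root split minimises total SSE over all candidate pairs
  set.seed(11)
  z2 <- rnorm(30)
  tr2 <- pairtree:::.grow_tree(d$X, z = z2, idx = 1:30, max_depth = 1,
                               n_candidate_genes = 4)
  if (tr2$var_i[1] > 0L) {
    got_sse <- oracle_sse(z2, d$X[, tr2$var_i[1]] <= d$X[, tr2$var_j[1]])
    all_pairs <- t(combn(4, 2))
    best_sse <- min(apply(all_pairs, 1, function(p)
      oracle_sse(z2, d$X[, p[1]] <= d$X[, p[2]])))
    expect_equal(got_sse, best_sse, tolerance = 1e-9)
  }
})

test_that("routing returns terminal payloads and is monotone-invariant", {
  d <- tiny_pair_data(n = 40, P = 5, seed = 6)
  fit <- rank_tree(d$X, d$y, seed = 2)
  p <- predict(fit, d$X, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 40))
  expect_identical(predict(fit, distort_rows(d$X, seed = 10)),
                   predict(fit, d$X))
  expect_error(predict(fit, unname(d$X[, 1:3])),
               class = "pairtree_dimension_error")
  expect_error(predict(fit, d$X[, 1:3]),
               class = "pairtree_gene_name_error")
})

test_that("tree growth is deterministic given a seed", {
  sim <- simulate_rank_data(n_samples = 50, n_genes = 10, n_pairs = 2,
                            seed = 5)
  f1 <- rank_tree(sim$data, n_candidate_genes = 3, seed = 42)
  f2 <- rank_tree(sim$data, n_candidate_genes = 3, seed = 42)
  expect_identical(f1$tree, f2$tree)
})
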