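# LogitBoost cost, working responses, node coefficients, and boosted fits.

test_that("working response is the negative gradient of the cost", {
  expect_equal(working_response(1, 0), 1)
  expect_equal(working_response(-1, 0), -1)
  expect_equal(working_response(1, 10), 2 / (1 + exp(20)), tolerance = 1e-12)
  expect_error(working_response(0, 1), class = "pairtree_label_coding_error")

  # numeric differentiation of C(y, F) on a grid
  h <- 1e-6
  for (y in c(-1, 1)) {
    for (f in seq(-4, 4, by = 0.25)) {
      num_grad <- (logit_cost_ref(y, f + h) - logit_cost_ref(y, f - h)) /
        (2 * h)
      expect_equal(working_response(y, f), -num_grad, tolerance = 1e-7)
    }
  }
  # always bounded by 2 with the sign of y
  set.seed(1)
  ys <- sample(c(-1, 1), 200, replace = TRUE)
  fs <- rnorm(200, sd = 3)
  z <- working_response(ys, fs)
  expect_true(all(abs(z) <= 2))
  expect_true(all(sign(z) == sign(ys)))
})

test_that("cost evaluation is stable for extreme scores", {
  expect_equal(logitboost_cost(1, 0), log(2))
  expect_false(is.infinite(logitboost_cost(1, -500)))
  expect_equal(logitboost_cost(-1, -500), logitboost_cost(1, 500))
})

test_that("node coefficient matches a numeric minimiser on converged nodes", {
  expect_equal(gamma_for_node(rep(1, 7)), 1)
  expect_equal(gamma_for_node(rep(0, 3)), 0)
  expect_error(gamma_for_node(numeric(0)), class = "pairtree_count_error")

  # the closed form is one Newton step from gamma = 0; its error is
  # quadratic in the node optimum, so agreement to 1e-4 is asserted on
  # near-converged nodes
  set.seed(2)
  for (node in near_converged_nodes(15)) {
    z <- working_response(node$y, node$f)
    expect_lt(abs(gamma_for_node(z) - node$gstar), 1e-4)
  }
})

test_that("boosting drives training cost below the intercept cost", {
  d <- tiny_pair_data(n = 60, P = 5, seed = 3)
  fit <- rank_boost(d$X, d$y, n_trees = 50, lambda = 0.1, max_depth = 1,
                    n_candidate_genes = 5, seed = 1)
  expect_equal(mean(predict(fit, d$X) == d$y), 1.0)
  expect_lt(fit$train_cost[length(fit$train_cost)], fit$train_cost[1])
  expect_true(all(diff(fit$train_cost) <= 1e-12))
})

test_that("cost is non-increasing when gamma comes from a numeric oracle", {
  # rebuild the boosting loop with golden-section node coefficients in
  # place of the closed form; the descent property must be intrinsic
  d <- tiny_pair_data(n = 40, P = 4, seed = 5)
  y <- ifelse(d$y == levels(d$y)[2], 1, -1)
  pbar <- mean(y == 1)
  Fv <- rep(0.5 * log(pbar / (1 - pbar)), 40)
  costs <- mean(logit_cost_ref(y, Fv))
  set.seed(4)
  for (m in 1:15) {
    z <- working_response(y, Fv)
    tr <- pairtree:::.grow_tree(d$X, z = z, idx = 1:40, max_depth = 2,
                                min_node_size = 5, n_candidate_genes = 4)
    ids <- pairtree:::route_forest_cpp(tr$var_i, tr$var_j, tr$left,
                                       tr$right, d$X, 1L)[, 1]
    gam <- rep(0, length(tr$var_i))
    for (t in which(tr$var_i == 0L)) {
      members <- ids == t
      if (any(members))
        gam[t] <- oracle_golden_min(function(g)
          sum(logit_cost_ref(y[members], Fv[members] + g)), -4, 4)
    }
    Fv <- Fv + 0.1 * gam[ids]
    costs <- c(costs, mean(logit_cost_ref(y, Fv)))
  }
  expect_true(all(diff(costs) <= 1e-10))
})

test_that("probabilities are logistic in F and flip with the label coding", {
  d <- tiny_pair_data(n = 50, P = 5, seed = 6)
  fit <- rank_boost(d$X, d$y, n_trees = 30, seed = 2)
  f <- predict(fit, d$X, type = "score")
  p <- predict(fit, d$X, type = "prob")
  expect_equal(unname(p[, 2]), 1 / (1 + exp(-2 * f)))
  expect_equal(unname(rowSums(p)), rep(1, 50))
  # reversing the level order negates every score exactly (same seed)
  yrev <- factor(d$y, levels = rev(levels(d$y)))
  fit2 <- rank_boost(d$X, yrev, n_trees = 30, seed = 2)
  expect_equal(predict(fit2, d$X, type = "score"), -f, tolerance = 1e-12)
})

test_that("invalid boosting parameters are rejected", {
  d <- tiny_pair_data(n = 20, P = 3, seed = 7)
  expect_error(rank_boost(d$X, d$y, lambda = 0),
               class = "pairtree_param_error")
  expect_error(rank_boost(d$X, d$y, lambda = 1.5),
               class = "pairtree_param_error")
  expect_error(rank_boost(d$X, d$y, n_trees = 0),
               class = "pairtree_param_error")
})

test_that("one-against-all handles three classes accurately", {
  s3 <- simulate_rank_data(n_samples = 300, n_genes = 30, n_classes = 3,
                           n_pairs = 5, flip_noise = 0, seed = 8)
  t3 <- simulate_rank_data(n_samples = 300, n_genes = 30, n_classes = 3,
                           n_pairs = 5, flip_noise = 0, seed = 9)
  fit <- rank_boost(s3$data, n_trees = 100, seed = 3)
  expect_length(fit$submodels, 3L)
  p <- predict(fit, t3$data, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 300), tolerance = 1e-12)
  expect_gte(mean(predict(fit, t3$data) == t3$data$labels), 0.9)
  # a class with a single sample cannot be one-against-all encoded
  y_bad <- factor(c("a", "b", "c")[c(1, 1, 1, 2, 2, 2, 3)])
  X_bad <- matrix(runif(7 * 4), 7, 4)
  expect_error(rank_boost(X_bad, y_bad, n_trees = 5),
               class = "pairtree_class_count_error")
})

test_that("boosted fits are reproducible and monotone-invariant", {
  sim <- simulate_rank_data(n_samples = 80, n_genes = 12, n_pairs = 2,
                            flip_noise = 0.05, seed = 10)
  f1 <- rank_boost(sim$data, n_trees = 40, seed = 5)
  f2 <- rank_boost(sim$data, n_trees = 40, seed = 5)
  expect_identical(f1$flat, f2$flat)
  X <- sim$data$values
  expect_identical(predict(f1, distort_rows(X, seed = 30), type = "prob"),
                   predict(f1, X, type = "prob"))
})
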