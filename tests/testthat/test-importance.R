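# Brier loss, gene-pair permutation importance, two-stage reduction.

test_that("Brier loss matches hand-computed values and validates rows", {
  expect_equal(brier_loss(c(1, 2), rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(brier_loss(c(1, 2), matrix(0.5, 2, 2)), 0.25)
  expect_equal(brier_loss(1, matrix(0.25, 1, 4)), 0.1875)
  expect_error(brier_loss(c(1, 2), rbind(c(0.9, 0.2), c(0.5, 0.5))),
               class = "pairtree_probability_error")
  expect_error(brier_loss(c("x", "y"),
                          matrix(0.5, 2, 2,
                                 dimnames = list(NULL, c("a", "b")))),
               class = "pairtree_unknown_label_error")
})

test_that("pairs untouched by every tree have exactly zero importance", {
  sim <- simulate_rank_data(n_samples = 100, n_genes = 12, n_pairs = 2,
                            flip_noise = 0.05, seed = 1)
  # restrict splits to the planted pairs, so everything else is unused
  fit <- rank_forest(sim$data, n_trees = 40,
                     pair_list = sim$truth$pair_index, seed = 2)
  vi <- pair_importance(fit, pairs = rbind(c(5, 6), c(7, 11), c(9, 12)))
  expect_identical(vi$importance, rep(0, 3))
})

test_that("planted pairs dominate noise pairs in importance", {
  sim <- simulate_rank_data(n_samples = 200, n_genes = 20, n_pairs = 2,
                            flip_noise = 0.05, seed = 3)
  fit <- rank_forest(sim$data, n_trees = 150, seed = 4)
  vi <- pair_importance(fit)
  tab <- paste(vi$i, vi$j)
  planted <- paste(sim$truth$pair_index[, 1], sim$truth$pair_index[, 2])
  imp_planted <- vi$importance[tab %in% planted]
  imp_noise <- vi$importance[!(vi$gene_i %in% colnames(sim$data$values)[1:4]) &
                             !(vi$gene_j %in% colnames(sim$data$values)[1:4])]
  expect_true(min(imp_planted) > 0.05)
  # pure-noise pairs carry at most weak leakage through marginals
  expect_gt(min(imp_planted), 2 * max(imp_noise))
  expect_lt(abs(mean(imp_noise)), 0.03)
})

test_that("importance centres on zero when labels carry no signal", {
  set.seed(5)
  X <- matrix(rlnorm(120 * 15, log(100), 1), 120, 15,
              dimnames = list(NULL, paste0("g", 1:15)))
  y <- factor(rep(c("A", "B"), 60))
  fit <- rank_forest(X, y, n_trees = 100, seed = 6)
  vi <- pair_importance(fit)
  expect_lt(abs(mean(vi$importance)), 0.02)
})

test_that("misclassification loss is an accepted importance criterion", {
  sim <- simulate_rank_data(n_samples = 150, n_genes = 12, n_pairs = 2,
                            flip_noise = 0.05, seed = 7)
  fit <- rank_forest(sim$data, n_trees = 100, seed = 8)
  vi <- pair_importance(fit, loss = "misclass")
  planted <- paste(sim$truth$pair_index[, 1], sim$truth$pair_index[, 2])
  expect_true(all(planted %in% paste(vi$i, vi$j)[1:6]))
})

test_that("gene importance aggregates pair importance by membership", {
  vi <- structure(
    data.frame(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"),
               i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
               importance = c(0.5, 0.2, -0.1)),
    class = c("pair_vimp", "data.frame"), loss = "brier",
    baseline_loss = 0.1)
  gi <- gene_importance(vi)
  expect_equal(gi$importance[gi$gene == "a"], 0.7)
  expect_equal(gi$importance[gi$gene == "b"], 0.4)
  expect_equal(gi$importance[gi$gene == "c"], 0.1)
})

test_that("two-stage reduction recovers informative genes and pairs", {
  sim <- simulate_rank_data(n_samples = 200, n_genes = 25, n_pairs = 3,
                            flip_noise = 0.05, seed = 9)
  red <- reduce_dimension(sim$data, n_trees = 150, seed = 10)
  informative <- as.vector(sim$truth$pairs)
  expect_true(all(informative %in% red$genes))
  expect_equal(red$report$n_genes, length(red$genes))
  expect_equal(red$report$n_pairs, nrow(red$pairs))
  planted <- apply(sim$truth$pairs, 1, paste, collapse = "-")
  kept <- apply(red$pairs, 1, paste, collapse = "-")
  expect_true(all(planted %in% kept))

  # reduction must not degrade the OOB Brier loss by more than a little
  full_loss <- attr(pair_importance(rank_forest(sim$data, n_trees = 150,
                                                seed = 10)),
                    "baseline_loss")
  red_loss <- attr(pair_importance(red$model), "baseline_loss")
  expect_lt(red_loss, full_loss + 0.05)

  # deterministic end to end
  red2 <- reduce_dimension(sim$data, n_trees = 150, seed = 10)
  expect_identical(red$genes, red2$genes)
  expect_identical(red$pairs, red2$pairs)
  expect_identical(predict(red, sim$data), predict(red2, sim$data))
})

test_that("degenerate selections fall back with a warning", {
  sim <- simulate_rank_data(n_samples = 80, n_genes = 10, n_pairs = 1,
                            rule = "single", seed = 11)
  ws <- capture_warnings(
    red <- reduce_dimension(sim$data, n_trees = 40, threshold = Inf,
                            seed = 12))
  expect_match(ws, "top|threshold", all = TRUE)
  expect_lte(length(red$genes), ceiling(sqrt(10)))
  expect_gte(length(red$genes), 1L)
})

test_that("boosting can drive the reduction stages", {
  sim <- simulate_rank_data(n_samples = 120, n_genes = 10, n_pairs = 2,
                            flip_noise = 0, seed = 13)
  red <- reduce_dimension(sim$data, engine = "boost", n_trees = 40,
                          seed = 14)
  expect_s3_class(red$model, "rank_boost")
  informative <- as.vector(sim$truth$pairs)
  expect_true(all(informative %in% red$genes))
})
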