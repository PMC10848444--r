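# Rule harvesting from forest terminal nodes, selection, and prediction.

test_that("every terminal node of a splitting tree becomes one rule", {
  sim <- simulate_rank_data(n_samples = 80, n_genes = 10, n_pairs = 2,
                            seed = 1)
  fit <- rank_forest(sim$data, n_trees = 20, seed = 2)
  rules <- extract_rules(fit)
  n_term <- sum(fit$flat$var_i == 0L)
  n_root_only <- sum(tapply(fit$flat$var_i, fit$flat$tree_id,
                            function(v) all(v == 0L)))
  expect_length(rules, n_term - n_root_only)
  expect_true(all(vapply(rules, function(r) nrow(r$cond) >= 1L, TRUE)))
  expect_true(all(vapply(rules, `[[`, 0, "oob_error") >= 0))
})

test_that("a depth-1 pure forest tree yields two one-condition rules", {
  d <- tiny_pair_data(n = 60, P = 3, seed = 3)
  suppressWarnings(
    fit <- rank_forest(d$X, d$y, n_trees = 1, max_depth = 1,
                       n_candidate_genes = 3, seed = 8))
  rules <- extract_rules(fit)
  expect_length(rules, 2L)
  expect_true(all(vapply(rules, function(r) nrow(r$cond), 0L) == 1L))
  expect_setequal(vapply(rules, `[[`, 0L, "predicted"), 1:2)
})

test_that("in-bag samples routed to a leaf satisfy its conjunction", {
  sim <- simulate_rank_data(n_samples = 60, n_genes = 10, n_pairs = 2,
                            flip_noise = 0.05, seed = 4)
  suppressWarnings(fit <- rank_forest(sim$data, n_trees = 10, seed = 5))
  rules <- extract_rules(fit)
  X <- sim$data$values
  for (r in rules[seq(1, length(rules), by = 7)]) {
    leaf_members <- which(fit$train_node_ids[, r$tree] == r$node &
                          fit$in_bag[, r$tree])
    if (!length(leaf_members)) next
    sat <- pairtree:::.rules_match(list(r), X)[leaf_members]
    expect_true(all(sat))
  }
})

test_that("selection orders by error, support, length and deduplicates", {
  classes <- c("A", "B"); genes <- paste0("g", 1:6)
  rules <- make_rules(list(
    make_rule(c(1, 2), 1L, 2L, oob_error = 0.1, support = 5, tree = 1),
    make_rule(c(1, 2, 3, 4), 1L, 2L, oob_error = 0.0, support = 3,
              tree = 2),
    make_rule(c(3, 4), 2L, 1L, oob_error = 0.1, support = 50, tree = 3),
    make_rule(c(2, 1), 2L, 1L, oob_error = 0.3, support = 9, tree = 4),
    make_rule(c(1, 2), 1L, 2L, oob_error = 0.2, support = 2, tree = 5)
  ), classes, genes)
  sel <- select_rules(rules, 3)
  # smoothed error ranks the well-supported clean rule first, then the
  # small perfect one; the duplicate condition set {1<2} collapses to its
  # better representative
  expect_equal(vapply(sel, `[[`, 0, "oob_error"), c(0.1, 0.0, 0.1))
  expect_equal(sel[[1]]$support, 50)
  expect_equal(sel[[3]]$support, 5)
  expect_warning(all_r <- select_rules(rules, 10), "distinct rules")
  expect_length(all_r, 4L)   # 5 candidates, one duplicate set
  expect_error(select_rules(rules, 0), class = "pairtree_param_error")
})

test_that("rule voting follows match/else/majority semantics", {
  classes <- c("A", "B"); genes <- c("u", "v", "w")
  X <- rbind(c(1, 2, 3),    # u < v
             c(2, 1, 3))    # u > v
  colnames(X) <- genes
  one <- make_rules(list(make_rule(c(1, 2), 1L, 2L)), classes, genes)
  expect_equal(as.character(predict(one, X)), c("A", "B"))

  # unanimous multi-rule votes decide regardless of tie policy
  many <- make_rules(list(
    make_rule(c(1, 2), 1L, 2L),
    make_rule(c(1, 3), 1L, 2L),
    make_rule(c(2, 3), 1L, 2L)), classes, genes)
  expect_equal(as.character(predict(many, X[1, , drop = FALSE])), "A")

  # three-class rules abstain when unmatched; unmatched-everywhere samples
  # fall back to the training majority
  classes3 <- c("A", "B", "C")
  r3 <- make_rules(list(make_rule(c(2, 1), 2L)), classes3, genes,
                   majority_class = 3L)
  expect_equal(as.character(predict(r3, X)), c("C", "B"))
})

test_that("formatting and parsing round-trip a rule", {
  genes <- c("NCOR1", "BNIP2", "DEF6", "LY6E")
  classes <- c("Liver", "HCC")
  rule <- make_rule(c(2, 1, 3, 4), 1L, 2L)
  txt <- format_rule(rule, genes, classes)
  expect_equal(txt, "IF BNIP2 < NCOR1 AND DEF6 < LY6E THEN Liver ELSE HCC")
  back <- parse_rule(txt, genes, classes)
  expect_equal(back$cond, rule$cond)
  expect_equal(back$predicted, rule$predicted)
  expect_equal(back$else_class, rule$else_class)
  # the > spelling parses to the swapped condition
  gt <- parse_rule("IF NCOR1 > BNIP2 THEN Liver ELSE HCC", genes, classes)
  expect_equal(gt$cond, matrix(c(2L, 1L), 1))
  # one condition renders without AND
  expect_false(grepl("AND", format_rule(make_rule(c(1, 2), 2L), genes,
                                        classes)))
  expect_error(parse_rule("nonsense", genes, classes),
               class = "pairtree_rule_parse_error")
})

test_that("a compact rule set approaches forest accuracy on planted data", {
  sim <- simulate_rank_data(n_samples = 200, n_genes = 30, n_pairs = 3,
                            flip_noise = 0.05, seed = 6)
  test <- simulate_rank_data(n_samples = 300, n_genes = 30, n_pairs = 3,
                             flip_noise = 0.05, seed = 7)
  fit <- rank_forest(sim$data, n_trees = 150, seed = 9)
  sel <- select_rules(extract_rules(fit, max_length = 3), 5)
  acc_forest <- mean(predict(fit, test$data) == test$data$labels)
  acc_rules <- mean(predict(sel, test$data) == test$data$labels)
  expect_gte(acc_rules, acc_forest - 0.05)
  # the top rule's conditions involve a planted pair
  top <- sel[[1]]
  planted <- apply(sim$truth$pair_index, 1, function(p)
    paste(sort(p), collapse = "-"))
  conds <- apply(top$cond, 1, function(p) paste(sort(p), collapse = "-"))
  expect_true(any(conds %in% planted))
})
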