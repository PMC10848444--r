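## Gradient boosting of rank-pair regression trees under the LogitBoost
## cost C(y, F) = log(1 + exp(-2 y F)), y in {-1, +1}.  Each iteration fits
## a shallow regression tree to the negative gradient (working response),
## replaces its terminal values by one-step Newton coefficients gamma, and
## updates the score F with shrinkage lambda.  Multi-class outcomes are
## handled one-against-all.

#' LogitBoost cost
#'
#' `C(y, F) = log(1 + exp(-2 y F))` for `y` in `{-1, +1}`; computed via
#' `log1p` in a numerically stable form.
#'
#' @param y Labels coded -1 / +1.
#' @param f Real-valued scores F(x).
#' @return Per-observation cost.
#' @export
logitboost_cost <- function(y, f) {
  u <- -2 * y * f
  ifelse(u > 30, u, log1p(exp(u)))
}

#' Working response of the LogitBoost cost
#'
#' The negative gradient `z = 2 y / (1 + exp(2 y F))`; always in `[-2, 2]`
#' with the sign of `y`, and near zero for well-classified points.
#'
#' @param y Labels coded -1 / +1.
#' @param f Current scores F(x).
#' @return Working responses, same length as `y`.
#' @export
working_response <- function(y, f) {
  if (!all(y %in% c(-1, 1)))
    pt_stop("y must be coded -1 / +1", "pairtree_label_coding_error")
  2 * y / (1 + exp(2 * y * f))
}

#' Terminal-node coefficient of a boosting iteration
#'
#' The one-step Newton minimiser of the node's total LogitBoost cost in the
#' offset gamma: `gamma = sum(z) / sum(|z| (2 - |z|))`, with the convention
#' `gamma = 0` when the denominator vanishes (all working responses zero).
#' The raw value is clipped to `[-clip, clip]` because the denominator can
#' be tiny at near-pure nodes.
#'
#' @param z Working responses of the training samples in the node.
#' @param clip Symmetric clipping bound (default 4).
#' @return The node coefficient gamma.
#' @export
gamma_for_node <- function(z, clip = 4) {
  if (length(z) == 0L)
    pt_stop("empty terminal node", "pairtree_count_error")
  den <- sum(abs(z) * (2 - abs(z)))
  if (den == 0) return(0)
  max(-clip, min(clip, sum(z) / den))
}

#' Fit a boosted rank-tree model (LogitBoost cost)
#'
#' Binary outcomes are coded -1 / +1 (the second factor level is +1) and the
#' score is initialised at the half log-odds of the base rate,
#' `F0 = 0.5 * log(pbar / (1 - pbar))`.  Each of the `n_trees` iterations
#' fits a depth-limited rank-pair regression tree to the working responses
#' (split by maximal reduction of within-daughter squared deviation),
#' replaces terminal values by [gamma_for_node()] coefficients, and updates
#' `F <- F + lambda * gamma(x)`.  Probabilities are
#' `1 / (1 + exp(-2 F))`.  With three or more classes, K one-against-all
#' binary models are fitted and their probabilities renormalised.
#'
#' @inheritParams rank_forest
#' @param n_trees Number of boosting iterations M.
#' @param lambda Shrinkage (learning rate) in (0, 1]; performance is robust
#'   over a wide range, default 0.1.
#' @param max_depth Depth of the weak learners; shallow trees (default 3)
#'   are standard in boosting.
#' @param min_node_size Default 5.
#' @param gamma_clip Clipping bound for node coefficients.
#' @return Object of class `"rank_boost"`.  Binary fits carry the
#'   per-iteration mean training cost in `$train_cost` (index 1 is the cost
#'   at F0).
#' @examples
#' sim <- simulate_rank_data(n_samples = 80, n_genes = 10, n_pairs = 1,
#'                           rule = "single", seed = 3)
#' fit <- rank_boost(sim$data, n_trees = 30, seed = 1)
#' fit
#' @export
rank_boost <- function(x, y = NULL, n_trees = 500L, lambda = 0.1,
                       max_depth = 3L, min_node_size = 5L,
                       n_candidate_genes = NULL, pair_list = NULL,
                       n_candidate_pairs = NULL, gamma_clip = 4,
                       seed = NULL, keep_data = TRUE) {
  d <- .xy_input(x, y)
  if (n_trees < 1L) pt_stop("n_trees must be >= 1", "pairtree_param_error")
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1)
    pt_stop("lambda must lie in (0, 1]", "pairtree_param_error")
  if (is.null(n_candidate_genes))
    n_candidate_genes <- ceiling(sqrt(ncol(d$X)))
  if (!is.null(pair_list)) {
    pair_list <- .resolve_pairs(pair_list, colnames(d$X))
    if (is.null(n_candidate_pairs))
      n_candidate_pairs <- max(2L, ceiling(sqrt(nrow(pair_list))))
  }
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)

  params <- list(n_trees = n_trees, lambda = lambda, max_depth = max_depth,
                 min_node_size = min_node_size,
                 n_candidate_genes = n_candidate_genes,
                 pair_list = pair_list,
                 n_candidate_pairs = n_candidate_pairs,
                 gamma_clip = gamma_clip, seed = seed)
  obj <- if (d$K == 2L) {
    .fit_boost_binary(d$X, d$yint == 2L, params)
  } else {
    if (any(table(d$y) < 2L))
      pt_stop("one-against-all boosting needs >= 2 samples per class",
              "pairtree_class_count_error")
    sub <- lapply(seq_len(d$K), function(k)
      .fit_boost_binary(d$X, d$yint == k, params))
    list(submodels = sub)
  }
  obj$classes <- d$classes
  obj$gene_names <- colnames(d$X)
  obj$params <- params
  obj$call <- match.call()
  if (keep_data) { obj$x <- d$X; obj$y <- d$y }
  class(obj) <- "rank_boost"
  obj
}

## One binary LogitBoost fit; `pos` is the logical indicator of the +1 class.
.fit_boost_binary <- function(X, pos, params) {
  N <- nrow(X)
  y <- ifelse(pos, 1, -1)
  pbar <- mean(pos)
  ## guard the degenerate all-one-class encodings that can arise in
  ## one-against-all splits of tiny classes
  pbar <- min(max(pbar, 1 / (2 * N)), 1 - 1 / (2 * N))
  F0 <- 0.5 * log(pbar / (1 - pbar))
  Fv <- rep(F0, N)
  trees <- vector("list", params$n_trees)
  cost <- numeric(params$n_trees + 1L)
  cost[1L] <- mean(logitboost_cost(y, Fv))
  for (m in seq_len(params$n_trees)) {
    z <- working_response(y, Fv)
    tr <- .grow_tree(X, z = z, idx = seq_len(N),
                     max_depth = params$max_depth,
                     min_node_size = params$min_node_size,
                     n_candidate_genes = params$n_candidate_genes,
                     pair_list = params$pair_list,
                     n_candidate_pairs = params$n_candidate_pairs)
    ids <- route_forest_cpp(tr$var_i, tr$var_j, tr$left, tr$right, X, 1L)[, 1L]
    gam <- rep(0, length(tr$var_i))
    for (t in which(tr$var_i == 0L)) {
      members <- ids == t
      if (any(members))
        gam[t] <- gamma_for_node(z[members], clip = params$gamma_clip)
    }
    tr$value <- gam
    trees[[m]] <- tr
    Fv <- Fv + params$lambda * gam[ids]
    cost[m + 1L] <- mean(logitboost_cost(y, Fv))
  }
  flat <- .flatten_trees(trees)
  list(F0 = F0, flat = flat,
       node_gamma = unlist(lapply(trees, `[[`, "value")),
       train_cost = cost, train_score = Fv)
}

## Scores F_M(x) of one binary submodel on new data.
.boost_scores <- function(model, X) {
  fl <- model$flat
  ids <- route_forest_cpp(fl$var_i, fl$var_j, fl$left, fl$right, X, fl$roots)
  lambda <- model$lambda
  model$F0 + lambda * rowSums(matrix(model$node_gamma[ids], nrow(X)))
}

#' Predict from a boosted rank-tree model
#'
#' Binary: `P(Y = level2 | x) = 1 / (1 + exp(-2 F_M(x)))`.  Multi-class:
#' one-against-all scores converted to probabilities and renormalised to
#' sum to 1.  Like the forest, predictions are invariant to strictly
#' increasing per-sample transforms of the expression values.
#'
#' @param object A [rank_boost()] fit.
#' @param newdata Matrix or [rank_data].
#' @param type `"response"`, `"prob"`, or `"score"` (the raw F values;
#'   binary models only).
#' @param ... Unused.
#' @return Factor of labels, probability matrix, or score vector.
#' @export
predict.rank_boost <- function(object, newdata,
                               type = c("response", "prob", "score"), ...) {
  type <- match.arg(type)
  X <- .newdata_matrix(newdata, object$gene_names)
  K <- length(object$classes)
  if (K == 2L) {
    sub <- object
    sub$lambda <- object$params$lambda
    f <- .boost_scores(sub, X)
    if (type == "score") return(f)
    p2 <- 1 / (1 + exp(-2 * f))
    prob <- cbind(1 - p2, p2)
  } else {
    if (type == "score")
      pt_stop("scores are defined for binary models only",
              "pairtree_param_error")
    prob <- vapply(object$submodels, function(s) {
      s$lambda <- object$params$lambda
      1 / (1 + exp(-2 * .boost_scores(s, X)))
    }, numeric(nrow(X)))
    prob <- matrix(prob, nrow(X), K)
    prob <- prob / rowSums(prob)
  }
  dimnames(prob) <- list(rownames(X), object$classes)
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.rank_boost <- function(x, ...) {
  K <- length(x$classes)
  cat("Boosted rank-tree model (LogitBoost cost)\n")
  cat(sprintf("  iterations: %d   lambda: %g   tree depth: %s\n",
              x$params$n_trees, x$params$lambda, x$params$max_depth))
  if (K == 2L) {
    cat(sprintf("  classes: %s (positive: %s)\n",
                paste(x$classes, collapse = ", "), x$classes[2L]))
    cat(sprintf("  training cost: %.4f at F0 -> %.4f after %d iterations\n",
                x$train_cost[1L], x$train_cost[length(x$train_cost)],
                x$params$n_trees))
  } else {
    cat(sprintf("  %d classes, one-against-all: %s\n", K,
                paste(x$classes, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.rank_boost <- function(object, ...) {
  out <- list(params = object$params, classes = object$classes)
  if (length(object$classes) == 2L) {
    out$train_cost_path <- object$train_cost
    if (!is.null(object$x))
      out$train_accuracy <-
        mean(predict(object, object$x) == object$y)
  }
  class(out) <- "summary.rank_boost"
  out
}

#' @export
print.summary.rank_boost <- function(x, ...) {
  cat(sprintf("rank_boost: M = %d, lambda = %g, depth = %s\n",
              x$params$n_trees, x$params$lambda, x$params$max_depth))
  if (!is.null(x$train_cost_path))
    cat(sprintf("  mean LogitBoost cost: %.4f -> %.4f\n",
                x$train_cost_path[1L],
                x$train_cost_path[length(x$train_cost_path)]))
  if (!is.null(x$train_accuracy))
    cat(sprintf("  training accuracy: %.4f\n", x$train_accuracy))
  invisible(x)
}
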