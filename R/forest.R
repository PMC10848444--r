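## Random rank forest: class-balanced bootstrap ensembles of rank-pair
## trees, with out-of-bag (OOB) prediction, error and confusion matrix.

#' Class-balanced bootstrap / subsample indices
#'
#' Draws `ceiling(N / K)` samples from each of the K classes, with
#' replacement (`"bootstrap"`, default) or without (`"subsample"`, capped at
#' the class size), so that expected class proportions in the bag are 1/K
#' regardless of the raw imbalance.  With a single class this reduces to the
#' plain bootstrap, for which the expected out-of-bag fraction of a sample
#' of size n is `(1 - 1/n)^n -> exp(-1) ~ 0.368`.
#'
#' @param labels Class label per sample (a single-level factor is allowed
#'   and gives the plain bootstrap).
#' @param sampling `"bootstrap"` or `"subsample"`.
#' @return Integer vector of drawn sample indices (a multiset under
#'   bootstrap).  The out-of-bag set is the complement of its unique values.
#' @export
class_balanced_bootstrap <- function(labels,
                                     sampling = c("bootstrap", "subsample")) {
  sampling <- match.arg(sampling)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L))
    pt_stop("every class must have at least one sample",
            "pairtree_class_count_error")
  N <- length(labels)
  per <- ceiling(N / nlevels(labels))
  idx <- unlist(lapply(levels(labels), function(cl) {
    members <- which(labels == cl)
    if (sampling == "bootstrap")
      members[sample.int(length(members), per, replace = TRUE)]
    else
      members[sample.int(length(members), min(per, length(members)))]
  }), use.names = FALSE)
  idx
}

#' Fit a random rank forest
#'
#' Grows `n_trees` rank-pair classification trees, each on an independent
#' class-balanced bootstrap with a fresh draw of `n_candidate_genes`
#' candidate genes at every node, and aggregates them by voting: the forest
#' probability of class k is the fraction of trees voting k.  Because each
#' tree sees only a bootstrap bag, the held-out (out-of-bag) samples give an
#' unbiased error estimate without cross-validation; it is computed at fit
#' time and shown by `print()`.
#'
#' @param x A [rank_data] object or samples x genes numeric matrix.
#' @param y Class labels (taken from `x` when it is a [rank_data]).
#' @param n_trees Number of trees M; 500 is sufficient for most datasets and
#'   going beyond 1000 rarely changes anything.
#' @param max_depth Maximum tree depth; forests use deep (unlimited) trees
#'   by default and rely on averaging to control variance.
#' @param min_node_size Minimum samples required to attempt a split is
#'   `2 * min_node_size`; default 1 (grow to purity).
#' @param n_candidate_genes Genes drawn per node (the q of the candidate
#'   set); default `ceiling(sqrt(P))`.  All unordered pairs within the draw
#'   are scored.
#' @param sampling `"bootstrap"` (default) or `"subsample"` within class.
#' @param pair_list Optional two-column matrix of gene index pairs; when
#'   given, node candidates are drawn from this list instead of from gene
#'   subsets (used by [reduce_dimension()] for the final reduced fit).
#' @param n_candidate_pairs Pairs drawn per node in `pair_list` mode;
#'   default `max(2, ceiling(sqrt(nrow(pair_list))))`.
#' @param seed Integer seed; the same seed, data and parameters reproduce
#'   the forest exactly.
#' @param keep_data Keep the training data in the object (needed by
#'   [pair_importance()] and [extract_rules()]); default `TRUE`.
#' @return Object of class `"rank_forest"` with components including
#'   `oob` (votes, probabilities, predictions, error, confusion) and
#'   `in_bag` (samples x trees logical).
#' @seealso [predict.rank_forest()], [extract_rules()], [pair_importance()]
#' @examples
#' sim <- simulate_rank_data(n_samples = 80, n_genes = 12, n_pairs = 2,
#'                           seed = 7)
#' fit <- rank_forest(sim$data, n_trees = 50, seed = 1)
#' fit
#' @export
rank_forest <- function(x, y = NULL, n_trees = 500L, max_depth = Inf,
                        min_node_size = 1L, n_candidate_genes = NULL,
                        sampling = c("bootstrap", "subsample"),
                        pair_list = NULL, n_candidate_pairs = NULL,
                        seed = NULL, keep_data = TRUE) {
  sampling <- match.arg(sampling)
  d <- .xy_input(x, y)
  if (n_trees < 1L) pt_stop("n_trees must be >= 1", "pairtree_param_error")
  P <- ncol(d$X)
  N <- nrow(d$X)
  if (is.null(n_candidate_genes)) n_candidate_genes <- ceiling(sqrt(P))
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

  trees <- vector("list", n_trees)
  in_bag <- matrix(FALSE, N, n_trees)
  for (m in seq_len(n_trees)) {
    bag <- class_balanced_bootstrap(d$y, sampling = sampling)
    in_bag[unique(bag), m] <- TRUE
    trees[[m]] <- .grow_tree(d$X, yint = d$yint, K = d$K, idx = bag,
                             max_depth = max_depth,
                             min_node_size = min_node_size,
                             n_candidate_genes = n_candidate_genes,
                             pair_list = pair_list,
                             n_candidate_pairs = n_candidate_pairs)
  }
  flat <- .flatten_trees(trees)
  counts <- do.call(rbind, lapply(trees, `[[`, "counts"))
  prob <- counts / rowSums(counts)
  obj <- structure(list(
    call = match.call(), n_trees = n_trees, classes = d$classes,
    gene_names = colnames(d$X),
    params = list(max_depth = max_depth, min_node_size = min_node_size,
                  n_candidate_genes = n_candidate_genes, sampling = sampling,
                  pair_list = pair_list,
                  n_candidate_pairs = n_candidate_pairs, seed = seed),
    flat = flat,
    node_counts = counts, node_prob = prob,
    node_class = max.col(counts, ties.method = "first"),
    in_bag = in_bag), class = "rank_forest")
  if (keep_data) { obj$x <- d$X; obj$y <- d$y }
  ids <- .route(obj, d$X)
  obj$train_node_ids <- ids
  obj$oob <- .oob_summary(obj, d$yint, ids)
  obj
}

## Concatenate per-tree flat arrays into one global arena with per-tree
## roots, plus bookkeeping consumed by rules and importance: per-tree gene
## usage and the canonical (i < j) pair used at every internal node.
.flatten_trees <- function(trees) {
  sizes <- vapply(trees, function(t) length(t$var_i), 0L)
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  shift <- function(v, o) ifelse(v > 0L, v + o, 0L)
  flat <- list(
    var_i = unlist(lapply(trees, `[[`, "var_i")),
    var_j = unlist(lapply(trees, `[[`, "var_j")),
    left = unlist(mapply(function(t, o) shift(t$left, o), trees, off,
                         SIMPLIFY = FALSE)),
    right = unlist(mapply(function(t, o) shift(t$right, o), trees, off,
                          SIMPLIFY = FALSE)),
    depth = unlist(lapply(trees, `[[`, "depth")),
    roots = off + 1L,
    tree_id = rep(seq_along(trees), sizes))
  internal <- flat$var_i > 0L
  flat$pair_nodes <- cbind(
    i = pmin(flat$var_i[internal], flat$var_j[internal]),
    j = pmax(flat$var_i[internal], flat$var_j[internal]),
    tree = flat$tree_id[internal])
  flat
}

## Terminal-node id for every (sample, tree); optional tree subset.
.route <- function(object, X, trees = NULL) {
  fl <- object$flat
  roots <- if (is.null(trees)) fl$roots else fl$roots[trees]
  route_forest_cpp(fl$var_i, fl$var_j, fl$left, fl$right, X, roots)
}

## OOB votes / probabilities / predictions / error from routed node ids.
.oob_summary <- function(object, yint, ids) {
  N <- nrow(ids); K <- length(object$classes)
  oob <- !object$in_bag
  cls <- matrix(object$node_class[ids], N)
  votes <- vapply(seq_len(K),
                  function(k) rowSums((cls == k) & oob), numeric(N))
  votes <- matrix(votes, N, K)
  n_oob <- rowSums(oob)
  has <- n_oob > 0L
  if (any(!has))
    warning(sprintf("%d sample(s) have no out-of-bag trees and are %s",
                    sum(!has), "excluded from the OOB error"))
  prob <- votes / pmax(n_oob, 1L)
  prob[!has, ] <- NA_real_
  pred <- ifelse(has, max.col(votes, ties.method = "first"), NA_integer_)
  err <- mean(pred[has] != yint[has])
  cm <- table(truth = factor(object$classes[yint[has]],
                             levels = object$classes),
              predicted = factor(object$classes[pred[has]],
                                 levels = object$classes))
  list(votes = votes, prob = prob,
       predicted = factor(object$classes[pred], levels = object$classes),
       n_oob_trees = n_oob, error = err, confusion = cm)
}

#' @export
print.rank_forest <- function(x, ...) {
  cat("Random rank forest\n")
  cat(sprintf("  trees: %d   genes: %d   candidate genes/node: %d\n",
              x$n_trees, length(x$gene_names),
              x$params$n_candidate_genes))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  OOB misclassification error: %.4f\n", x$oob$error))
  cat("  OOB confusion matrix:\n")
  print(x$oob$confusion)
  invisible(x)
}

#' @export
summary.rank_forest <- function(object, ...) {
  internal <- object$flat$var_i > 0L
  out <- list(
    n_trees = object$n_trees,
    oob_error = object$oob$error,
    oob_accuracy = 1 - object$oob$error,
    confusion = object$oob$confusion,
    mean_nodes_per_tree = length(object$flat$var_i) / object$n_trees,
    mean_depth = mean(tapply(object$flat$depth, object$flat$tree_id, max)),
    n_distinct_pairs_used =
      nrow(unique(object$flat$pair_nodes[, 1:2, drop = FALSE])))
  class(out) <- "summary.rank_forest"
  out
}

#' @export
print.summary.rank_forest <- function(x, ...) {
  cat(sprintf(
    "Random rank forest: %d trees, OOB accuracy %.4f (error %.4f)\n",
    x$n_trees, x$oob_accuracy, x$oob_error))
  cat(sprintf("  mean nodes/tree %.1f, mean depth %.1f, %d distinct %s\n",
              x$mean_nodes_per_tree, x$mean_depth, x$n_distinct_pairs_used,
              "gene pairs used"))
  print(x$confusion)
  invisible(x)
}

#' Predict from a random rank forest
#'
#' Each tree routes the sample by its pair comparisons and votes its
#' terminal-node majority class; the forest probability of class k is the
#' vote fraction (rows sum to exactly 1).  Predictions depend only on
#' within-sample gene order, so any strictly increasing per-sample transform
#' of the input (platform change, log, quantile scaling) leaves them
#' bit-identical.
#'
#' @param object A [rank_forest()] fit.
#' @param newdata Matrix or [rank_data]; columns matched to training genes
#'   by name when named.
#' @param type `"response"` (labels), `"prob"` (vote fractions) or
#'   `"votes"` (raw counts).
#' @param ... Unused.
#' @return Factor, or samples x classes matrix.  Label ties break to the
#'   lowest class index.
#' @export
predict.rank_forest <- function(object, newdata,
                                type = c("response", "prob", "votes"), ...) {
  type <- match.arg(type)
  X <- .newdata_matrix(newdata, object$gene_names)
  ids <- .route(object, X)
  cls <- matrix(object$node_class[ids], nrow(X))
  K <- length(object$classes)
  votes <- vapply(seq_len(K), function(k) rowSums(cls == k),
                  numeric(nrow(X)))
  votes <- matrix(votes, nrow(X), K,
                  dimnames = list(rownames(X), object$classes))
  if (type == "votes") return(votes)
  if (type == "prob") return(votes / object$n_trees)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Out-of-bag predictions of a rank forest
#'
#' Returns the fit-time OOB summary: each training sample is predicted only
#' by the trees whose bootstrap bag excluded it.  Samples never out of bag
#' (possible at very small `n_trees`) carry `NA` probabilities and are
#' excluded from the error.
#'
#' @param object A [rank_forest()] fit.
#' @return List with `prob`, `votes`, `predicted`, `n_oob_trees`, `error`,
#'   `confusion`.
#' @export
oob_predictions <- function(object) {
  stopifnot(inherits(object, "rank_forest"))
  object$oob
}
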