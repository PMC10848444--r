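## Single rank-based trees.
##
## Every internal node compares two genes within the sample: left child is
## {x_i <= x_j}, right child is {x_i > x_j}.  Classification trees maximise
## the Gini split statistic g; regression trees (the boosting weak learner)
## maximise the equivalent sum-of-squares statistic.  A tree of one split is
## exactly a top-scoring-pair classifier.

#' Gini impurity of a class-proportion vector
#'
#' `1 - sum(p_k^2)`, zero for a pure node and maximal (`1 - 1/K`) for the
#' uniform mix.
#'
#' @param p Non-negative proportions summing to 1 (tolerance `1e-9`).
#' @return Impurity in `[0, 1)`.
#' @examples
#' gini_impurity(c(0.3, 0.7))  # 0.42
#' @export
gini_impurity <- function(p) {
  if (any(p < 0))
    pt_stop("proportions must be non-negative", "pairtree_proportion_error")
  if (abs(sum(p) - 1) > 1e-9)
    pt_stop("proportions must sum to 1", "pairtree_proportion_error")
  1 - sum(p^2)
}

#' Gini split statistic for a candidate daughter partition
#'
#' For class counts `n_k` at a node and counts `n_kl` sent to the left
#' daughter, returns
#' `g = (1/n) * (sum_k n_kl^2 / n_l + sum_k (n_k - n_kl)^2 / (n - n_l))`.
#' Maximising `g` over candidate pairs is equivalent to minimising the
#' sample-weighted Gini impurity of the two daughters: algebraically
#' `g = 1 - (n_l/n) * phi(p_l) - (n_r/n) * phi(p_r)`.
#'
#' @param left_counts Per-class counts in the left daughter.
#' @param total_counts Per-class counts at the parent node.
#' @return The split statistic, a real in `(0, 1]`.
#' @examples
#' split_statistic_g(c(2, 0), c(2, 2))  # 1: a pure separation
#' @export
split_statistic_g <- function(left_counts, total_counts) {
  if (length(left_counts) != length(total_counts) ||
      any(left_counts < 0) || any(left_counts > total_counts))
    pt_stop("left counts must satisfy 0 <= left <= total elementwise",
            "pairtree_count_error")
  n <- sum(total_counts)
  nl <- sum(left_counts)
  if (nl == 0 || nl == n)
    pt_stop("both daughter nodes must be non-empty", "pairtree_count_error")
  (sum(left_counts^2) / nl + sum((total_counts - left_counts)^2) / (n - nl)) / n
}

## Score all candidate pairs at a node in one shot.
## Classification: returns g per pair; regression: SSE reduction per pair.
## Pairs producing an empty daughter score -Inf.
.score_pairs <- function(X, idx, pi, pj, yhot = NULL, z = NULL) {
  ind <- X[idx, pi, drop = FALSE] <= X[idx, pj, drop = FALSE]
  n <- length(idx)
  nl <- colSums(ind)
  ok <- nl > 0 & nl < n
  if (!is.null(yhot)) {
    nkl <- crossprod(yhot[idx, , drop = FALSE], ind)   # K x Q
    nk <- colSums(yhot[idx, , drop = FALSE])
    sc <- (colSums(nkl^2) / nl + colSums((nk - nkl)^2) / (n - nl)) / n
  } else {
    zi <- z[idx]
    sl <- as.vector(crossprod(zi, ind))
    S <- sum(zi)
    sc <- sl^2 / nl + (S - sl)^2 / (n - nl) - S^2 / n
  }
  sc[!ok] <- -Inf
  list(score = sc, ind = ind, nl = nl)
}

## Candidate pairs for one node.  Default mode samples a fresh set of Q'
## candidate genes without replacement and searches all unordered pairs
## within it; pair-list mode samples rows of an explicit pair list (used by
## the reduced ensemble).  Candidates are returned in lexicographic (i, j)
## order so that which.max resolves score ties deterministically towards the
## lowest pair.
.candidate_pairs <- function(P, n_candidate_genes, pair_list,
                             n_candidate_pairs) {
  if (is.null(pair_list)) {
    q <- min(n_candidate_genes, P)
    genes <- sort(sample.int(P, q))
    if (q < 2L) return(NULL)
    cmb <- combn(genes, 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  } else {
    np <- nrow(pair_list)
    take <- if (np <= n_candidate_pairs) seq_len(np)
            else sample.int(np, n_candidate_pairs)
    pr <- pair_list[take, , drop = FALSE]
    pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  }
}

## Grow one rank-pair tree and return it in flat-array form:
## var_i/var_j (0 = terminal), left/right child ids (0 = none), depth,
## counts (K-column matrix of class counts per node) or value (node mean of
## the regression response).  Consumes the caller's RNG stream.
.grow_tree <- function(X, yint = NULL, K = NULL, z = NULL, idx,
                       max_depth = Inf, min_node_size = 1L,
                       n_candidate_genes = NULL, pair_list = NULL,
                       n_candidate_pairs = NULL) {
  P <- ncol(X)
  classification <- !is.null(yint)
  yhot <- NULL
  if (classification) {
    yhot <- matrix(0, nrow(X), K)
    yhot[cbind(seq_len(nrow(X)), yint)] <- 1
  }
  e <- new.env(parent = emptyenv())
  e$vi <- integer(0); e$vj <- integer(0)
  e$lc <- integer(0); e$rc <- integer(0); e$dp <- integer(0)
  e$cn <- list(); e$vl <- numeric(0)

  new_node <- function(idx, depth) {
    id <- length(e$vi) + 1L
    e$vi[id] <- 0L; e$vj[id] <- 0L; e$lc[id] <- 0L; e$rc[id] <- 0L
    e$dp[id] <- depth
    if (classification) e$cn[[id]] <- tabulate(yint[idx], K)
    else e$vl[id] <- mean(z[idx])
    id
  }

  build <- function(idx, depth) {
    id <- new_node(idx, depth)
    n <- length(idx)
    pure <- if (classification) max(e$cn[[id]]) == n
            else all(z[idx] == z[idx[1L]])
    if (pure || depth >= max_depth || n < 2L * min_node_size) return(id)
    pr <- .candidate_pairs(P, n_candidate_genes, pair_list, n_candidate_pairs)
    if (is.null(pr) || nrow(pr) == 0L) return(id)
    sc <- .score_pairs(X, idx, pr[, 1L], pr[, 2L], yhot = yhot, z = z)
    best <- which.max(sc$score)
    no_split <- if (classification) sum(e$cn[[id]]^2) / n^2 else 0
    if (!is.finite(sc$score[best]) || sc$score[best] <= no_split + 1e-12)
      return(id)
    go_left <- sc$ind[, best]
    e$vi[id] <- pr[best, 1L]; e$vj[id] <- pr[best, 2L]
    e$lc[id] <- build(idx[go_left], depth + 1L)
    e$rc[id] <- build(idx[!go_left], depth + 1L)
    id
  }

  build(idx, 0L)
  out <- list(var_i = e$vi, var_j = e$vj, left = e$lc, right = e$rc,
              depth = e$dp)
  if (classification) out$counts <- do.call(rbind, e$cn)
  else out$value <- e$vl
  out
}

## Best single pair split at a node, by exhaustive search within a candidate
## gene set (Gini statistic).  Returns NULL when no admissible split strictly
## improves over the no-split value.  This is the per-node search the trees
## use, exposed internally for oracle tests.
.best_pair_split <- function(X, yint, K, idx, candidate_genes) {
  genes <- sort(candidate_genes)
  if (length(genes) < 2L)
    pt_stop("need at least two candidate genes", "pairtree_candidate_error")
  cmb <- combn(genes, 2L)
  yhot <- matrix(0, nrow(X), K)
  yhot[cbind(seq_len(nrow(X)), yint)] <- 1
  sc <- .score_pairs(X, idx, cmb[1L, ], cmb[2L, ], yhot = yhot)
  n <- length(idx)
  nk <- tabulate(yint[idx], K)
  best <- which.max(sc$score)
  if (!is.finite(sc$score[best]) || sc$score[best] <= sum(nk^2) / n^2 + 1e-12)
    return(NULL)
  c(i = cmb[1L, best], j = cmb[2L, best])
}

#' Fit a single rank-based tree
#'
#' Grows one classification tree on within-sample gene-pair order relations.
#' With `max_depth = 1` this is a top-scoring-pair classifier; unrestricted
#' depth memorises any tie-free separable training set.  Mostly useful for
#' inspection and teaching — the ensembles ([rank_forest()], [rank_boost()])
#' are the predictors of practical interest.
#'
#' @param x A [rank_data] object or samples x genes matrix.
#' @param y Class labels (taken from `x` when it is a [rank_data]).
#' @param max_depth Maximum tree depth (root = 0).
#' @param min_node_size A node with fewer than `2 * min_node_size` samples is
#'   not split.
#' @param n_candidate_genes Candidate genes drawn afresh at each node;
#'   default all genes (exhaustive pair search).
#' @param seed Integer seed for the candidate draws.
#' @return Object of class `"rank_tree"`.
#' @export
rank_tree <- function(x, y = NULL, max_depth = Inf, min_node_size = 1L,
                      n_candidate_genes = NULL, seed = NULL) {
  d <- .xy_input(x, y)
  if (is.null(n_candidate_genes)) n_candidate_genes <- ncol(d$X)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)
  tr <- .grow_tree(d$X, yint = d$yint, K = d$K, idx = seq_len(nrow(d$X)),
                   max_depth = max_depth, min_node_size = min_node_size,
                   n_candidate_genes = n_candidate_genes)
  structure(list(tree = tr, classes = d$classes,
                 gene_names = colnames(d$X), call = match.call()),
            class = "rank_tree")
}

#' @export
print.rank_tree <- function(x, ...) {
  nterm <- sum(x$tree$var_i == 0L)
  cat(sprintf(
    "rank_tree: %d nodes (%d terminal), depth %d, classes: %s\n",
    length(x$tree$var_i), nterm, max(x$tree$depth),
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict from a single rank-based tree
#'
#' @param object A [rank_tree()] fit.
#' @param newdata Matrix or [rank_data] with the training genes.
#' @param type `"response"` for class labels, `"prob"` for terminal-node
#'   class proportions.
#' @param ... Unused.
#' @return Factor of labels or a samples x classes probability matrix.
#' @export
predict.rank_tree <- function(object, newdata,
                              type = c("response", "prob"), ...) {
  type <- match.arg(type)
  X <- .newdata_matrix(newdata, object$gene_names)
  tr <- object$tree
  ids <- route_forest_cpp(tr$var_i, tr$var_j, tr$left, tr$right, X, 1L)[, 1L]
  prob <- tr$counts / rowSums(tr$counts)
  p <- prob[ids, , drop = FALSE]
  dimnames(p) <- list(rownames(X), object$classes)
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

## Normalise (x, y) input shared by all fitters.
.xy_input <- function(x, y) {
  if (inherits(x, "rank_data")) {
    if (is.null(y)) y <- x$labels
    X <- x$values
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
    if (is.null(y)) pt_stop("'y' is required when 'x' is a plain matrix",
                            "pairtree_label_length_error")
  }
  if (anyNA(X))
    pt_stop("expression matrix contains missing values",
            "pairtree_missing_value_error")
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  if (length(y) != nrow(X))
    pt_stop("length of 'y' must equal the number of samples",
            "pairtree_label_length_error")
  list(X = X, y = y, yint = as.integer(y), K = nlevels(y),
       classes = levels(y))
}
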