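## Permutation importance for gene pairs and the two-stage dimension
## reduction: select genes by aggregated pair importance, reselect pairs on
## the reduced gene set, then fit the final ensemble restricted to the
## selected pairs.

#' Brier loss of probabilistic class predictions
#'
#' `mean over samples of (1/K) * sum_k (1{Y = k} - phat_k)^2`, in `[0, 1]`.
#'
#' @param truth True labels (factor or values matching `colnames(prob)` /
#'   class indices).
#' @param prob Samples x classes probability matrix; rows must sum to 1
#'   within `1e-6`.
#' @return The mean Brier loss.
#' @examples
#' brier_loss(c(1, 2), rbind(c(1, 0), c(0, 1)))   # 0
#' brier_loss(c(1, 2), matrix(0.5, 2, 2))         # 0.25
#' @export
brier_loss <- function(truth, prob) {
  prob <- as.matrix(prob)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    pt_stop("probability rows must sum to 1", "pairtree_probability_error")
  K <- ncol(prob)
  yi <- if (is.numeric(truth) && is.null(colnames(prob)))
    as.integer(truth) else match(as.character(truth), colnames(prob))
  if (anyNA(yi) || any(yi < 1L) || any(yi > K))
    pt_stop("labels do not match probability columns",
            "pairtree_unknown_label_error")
  onehot <- matrix(0, nrow(prob), K)
  onehot[cbind(seq_len(nrow(prob)), yi)] <- 1
  mean(rowSums((onehot - prob)^2) / K)
}

## Per-(sample, tree) loss matrix from routed terminal ids, vectorised so
## that a full swap scan stays fast.  For Brier on single-tree terminal
## proportions: (sum_k p_k^2 - 2 p_true + 1) / K.
.tree_losses <- function(object, ids, yint, loss) {
  nn <- nrow(object$node_prob)
  if (loss == "brier") {
    sumsq <- rowSums(object$node_prob^2)
    ptrue <- object$node_prob[ids + (yint - 1L) * nn]
    (matrix(sumsq[ids], nrow(ids)) - 2 * matrix(ptrue, nrow(ids)) + 1) /
      length(object$classes)
  } else {
    (matrix(object$node_class[ids], nrow(ids)) != yint) * 1
  }
}

#' Permutation importance of gene pairs
#'
#' The importance of pair (i, j) is the increase in out-of-bag loss when
#' the relationship of genes i and j is reversed, operationalised by
#' swapping columns i and j of the OOB data before routing: for each tree,
#' the loss over its own OOB samples is computed with original and swapped
#' columns, and the importance is the average over trees of
#' (swapped - baseline).  Positive values mean the pair's within-sample
#' order carries signal; pairs used by no tree are exactly 0.  (The sign
#' convention is "bigger = more important"; the difference is reported as
#' permuted minus baseline.)
#'
#' @param object A [rank_forest()] fit with `keep_data = TRUE`.
#' @param pairs Two-column matrix of gene indices or names; default all
#'   pairs used by at least one tree.
#' @param loss `"brier"` (on terminal-node class proportions, default) or
#'   `"misclass"` (on tree votes).
#' @return Object of class `"pair_vimp"`: a data frame with `gene_i`,
#'   `gene_j`, `importance`, sorted by decreasing importance, with the
#'   per-tree mean baseline loss in `attr(, "baseline_loss")`.
#' @export
pair_importance <- function(object, pairs = NULL,
                            loss = c("brier", "misclass")) {
  stopifnot(inherits(object, "rank_forest"))
  loss <- match.arg(loss)
  if (is.null(object$x))
    pt_stop("forest was fitted with keep_data = FALSE",
            "pairtree_param_error")
  gn <- object$gene_names
  P <- length(gn)
  used <- unique(object$flat$pair_nodes[, 1:2, drop = FALSE])
  if (is.null(pairs)) {
    pairs <- used[order(used[, 1L], used[, 2L]), , drop = FALSE]
  } else {
    pairs <- .resolve_pairs(pairs, gn)
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
  }
  yint <- as.integer(object$y)
  oob <- !object$in_bag
  n_oob <- colSums(oob)
  valid <- n_oob > 0L
  ids0 <- object$train_node_ids
  L0 <- .tree_losses(object, ids0, yint, loss)
  base_tree <- colSums(L0 * oob) / pmax(n_oob, 1L)
  gene_use <- matrix(FALSE, P, object$n_trees)
  pn <- object$flat$pair_nodes
  gene_use[cbind(pn[, 1L], pn[, 3L])] <- TRUE
  gene_use[cbind(pn[, 2L], pn[, 3L])] <- TRUE
  used_key <- paste(used[, 1L], used[, 2L])

  imp <- numeric(nrow(pairs))
  M_eff <- sum(valid)
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1L]; j <- pairs[q, 2L]
    if (!(paste(i, j) %in% used_key)) next        # untouched by any tree
    aff <- which((gene_use[i, ] | gene_use[j, ]) & valid)
    if (length(aff) == 0L) next
    Xs <- object$x
    Xs[, c(i, j)] <- Xs[, c(j, i)]
    ids_sw <- .route(object, Xs, trees = aff)
    Ls <- .tree_losses(object, ids_sw, yint, loss)
    sw_tree <- colSums(Ls * oob[, aff, drop = FALSE]) / n_oob[aff]
    imp[q] <- sum(sw_tree - base_tree[aff]) / M_eff
  }
  out <- data.frame(gene_i = gn[pairs[, 1L]], gene_j = gn[pairs[, 2L]],
                    i = pairs[, 1L], j = pairs[, 2L], importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$i, out$j), ]
  rownames(out) <- NULL
  structure(out, class = c("pair_vimp", "data.frame"), loss = loss,
            baseline_loss = mean(base_tree[valid]))
}

#' @export
print.pair_vimp <- function(x, max_pairs = 15L, ...) {
  cat(sprintf("gene-pair permutation importance (%s loss, baseline %.4f)\n",
              attr(x, "loss"), attr(x, "baseline_loss")))
  print.data.frame(head(x, max_pairs))
  if (nrow(x) > max_pairs) cat(sprintf("... and %d more\n",
                                       nrow(x) - max_pairs))
  invisible(x)
}

#' @export
plot.pair_vimp <- function(x, top = 20L, ...) {
  d <- head(x, top)
  graphics::dotchart(rev(d$importance),
                     labels = rev(paste(d$gene_i, d$gene_j, sep = " ~ ")),
                     xlab = sprintf("importance (%s loss increase)",
                                    attr(x, "loss")), ...)
  invisible(x)
}

#' Per-gene importance aggregated from pair importance
#'
#' A gene's importance is the sum, over all tree-used pairs containing it,
#' of the pair importances — the aggregation used by the gene-selection
#' stage of [reduce_dimension()].
#'
#' @param vimp A [pair_importance()] table.
#' @return Data frame with `gene` and `importance`, sorted decreasing.
#' @export
gene_importance <- function(vimp) {
  stopifnot(inherits(vimp, "pair_vimp"))
  long <- data.frame(gene = c(vimp$gene_i, vimp$gene_j),
                     importance = rep(vimp$importance, 2L),
                     stringsAsFactors = FALSE)
  agg <- aggregate(importance ~ gene, data = long, FUN = sum)
  agg <- agg[order(-agg$importance), ]
  rownames(agg) <- NULL
  agg
}

## Pair importance for a boosted model via V-fold held-out loss: for each
## fold, the model is fitted on the remainder and the Brier loss on the
## fold is compared with / without the column swap.  Pairs unused by a
## fold's model contribute 0 for that fold.
.boost_pair_importance <- function(X, y, pairs = NULL, n_folds = 5L,
                                   loss = "brier", ...) {
  y <- droplevels(as.factor(y))
  folds <- .balanced_folds(y, n_folds)
  gn <- colnames(X)
  P <- ncol(X)
  acc <- NULL
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- rank_boost(X[tr, , drop = FALSE], y[tr], ...)
    used <- unique(rbind(
      if (length(fit$classes) == 2L) fit$flat$pair_nodes[, 1:2, drop = FALSE]
      else do.call(rbind, lapply(fit$submodels, function(s)
        s$flat$pair_nodes[, 1:2, drop = FALSE]))))
    prs <- if (is.null(pairs)) used else pairs
    base <- brier_loss(y[te], predict(fit, X[te, , drop = FALSE],
                                      type = "prob"))
    res <- data.frame(i = prs[, 1L], j = prs[, 2L],
                      diff = 0, fold = f)
    uk <- paste(used[, 1L], used[, 2L])
    for (q in seq_len(nrow(prs))) {
      if (!(paste(prs[q, 1L], prs[q, 2L]) %in% uk)) next
      Xs <- X[te, , drop = FALSE]
      Xs[, c(prs[q, 1L], prs[q, 2L])] <- Xs[, c(prs[q, 2L], prs[q, 1L])]
      res$diff[q] <- brier_loss(y[te], predict(fit, Xs, type = "prob")) - base
    }
    acc <- rbind(acc, res)
  }
  agg <- aggregate(diff ~ i + j, data = acc, FUN = mean)
  out <- data.frame(gene_i = gn[agg$i], gene_j = gn[agg$j],
                    i = agg$i, j = agg$j, importance = agg$diff,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$i, out$j), ]
  rownames(out) <- NULL
  structure(out, class = c("pair_vimp", "data.frame"), loss = loss,
            baseline_loss = NA_real_)
}

#' Two-stage dimension reduction and final ensemble fit
#'
#' High dimension is the practical obstacle of pair-based trees: P genes
#' imply O(P^2) candidate pairs.  The reduction runs in two ensemble
#' stages: (1) fit an ensemble on all genes, score every tree-used pair by
#' permutation importance, aggregate to genes, and keep genes with positive
#' importance; (2) refit on the kept genes, rescore pairs, and keep pairs
#' with positive importance; the final ensemble is then fitted with node
#' candidates drawn only from the selected pairs.
#'
#' @param x A [rank_data] or samples x genes matrix.
#' @param y Class labels.
#' @param engine `"forest"` (default; importance comes free from OOB data)
#'   or `"boost"` (importance from 5-fold held-out loss).
#' @param loss Loss for the forest importance (`"brier"` or `"misclass"`).
#' @param threshold Importance threshold for keeping genes and pairs
#'   (default 0, i.e. keep strictly positive).
#' @param n_trees Trees/iterations per stage.
#' @param seed Integer seed driving all three stages.
#' @param ... Further arguments passed to [rank_forest()] / [rank_boost()].
#' @return Object of class `"reduced_rank_fit"`: the final `model`, the
#'   selected `genes` and `pairs` (gene-name matrix), a `report` data frame
#'   with `n_genes` and `n_pairs`, and both stage importance tables.
#' @details If no gene scores above the threshold (e.g. pure-noise data),
#'   the top `ceiling(sqrt(P))` genes by importance are kept with a
#'   warning.  If fewer than two genes survive, no pairs can be formed and
#'   the stage-2 model is returned as final, with a warning.
#' @export
reduce_dimension <- function(x, y = NULL, engine = c("forest", "boost"),
                             loss = c("brier", "misclass"), threshold = 0,
                             n_trees = 500L, seed = NULL, ...) {
  engine <- match.arg(engine)
  loss <- match.arg(loss)
  d <- .xy_input(x, y)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)
  seeds <- sample.int(.Machine$integer.max, 4L)
  P <- ncol(d$X)

  fit_stage <- function(X, pair_list = NULL) {
    if (engine == "forest")
      rank_forest(X, d$y, n_trees = n_trees, pair_list = pair_list,
                  seed = seeds[if (is.null(pair_list)) 1L else 3L], ...)
    else
      rank_boost(X, d$y, n_trees = n_trees, pair_list = pair_list,
                 seed = seeds[if (is.null(pair_list)) 1L else 3L], ...)
  }
  imp_stage <- function(fit, X, sd) {
    if (engine == "forest") pair_importance(fit, loss = loss)
    else {
      set.seed(sd)
      .boost_pair_importance(X, d$y, n_trees = n_trees, ...)
    }
  }

  ## stage 1: gene selection
  fit1 <- fit_stage(d$X)
  vimp1 <- imp_stage(fit1, d$X, seeds[2L])
  gimp <- gene_importance(vimp1)
  genes <- gimp$gene[gimp$importance > threshold]
  if (length(genes) == 0L) {
    warning("no gene scored above the threshold; keeping the top ",
            ceiling(sqrt(P)), " genes by importance")
    genes <- head(gimp$gene, ceiling(sqrt(P)))
  }
  genes <- intersect(colnames(d$X), genes)      # restore column order
  X2 <- d$X[, genes, drop = FALSE]

  ## stage 2: pair selection on the reduced gene set
  if (length(genes) < 2L) {
    warning("fewer than two genes selected; no pairs can be formed")
    fit2 <- fit1
    vimp2 <- vimp1[0L, ]
    sel_pairs <- matrix(integer(0), 0L, 2L)
    final <- fit1
  } else {
    fit2 <- fit_stage(X2)
    vimp2 <- imp_stage(fit2, X2, seeds[2L])
    keep <- vimp2$importance > threshold
    sel_pairs <- cbind(vimp2$i[keep], vimp2$j[keep])
    if (nrow(sel_pairs) == 0L) {
      warning("no pair scored above the threshold; ",
              "returning the reduced-gene ensemble")
      final <- fit2
    } else {
      final <- fit_stage(X2, pair_list = sel_pairs)
    }
  }
  pair_names <- if (nrow(sel_pairs)) {
    cbind(gene_i = colnames(X2)[sel_pairs[, 1L]],
          gene_j = colnames(X2)[sel_pairs[, 2L]])
  } else matrix(character(0), 0L, 2L,
                dimnames = list(NULL, c("gene_i", "gene_j")))
  structure(list(
    model = final, engine = engine, genes = genes, pairs = pair_names,
    report = data.frame(n_genes = length(genes),
                        n_pairs = nrow(pair_names)),
    stage1_importance = vimp1, stage2_importance = vimp2,
    call = match.call()), class = "reduced_rank_fit")
}

#' @export
print.reduced_rank_fit <- function(x, ...) {
  cat(sprintf("Two-stage reduced %s ensemble\n",
              if (x$engine == "forest") "rank-forest" else "boosted"))
  cat(sprintf("  selected genes: %d   selected gene pairs: %d\n",
              x$report$n_genes, x$report$n_pairs))
  if (inherits(x$model, "rank_forest"))
    cat(sprintf("  final model OOB error: %.4f\n", x$model$oob$error))
  invisible(x)
}

#' @export
predict.reduced_rank_fit <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "rank_data")) newdata$values
       else as.matrix(newdata)
  if (!is.null(colnames(m)) && all(object$genes %in% colnames(m)) &&
      !identical(colnames(m), object$model$gene_names))
    m <- m[, object$model$gene_names, drop = FALSE]
  predict(object$model, m, ...)
}
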