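## Interpretable if-then rules harvested from forest terminal nodes.
## Every root-to-leaf path is a conjunction of pair-order conditions; its
## quality is the misclassification error of the leaf's majority class over
## the source tree's out-of-bag samples that satisfy the conjunction.

## Internal representation of one rule: list(cond = matrix[i, j] meaning
## "x_i < x_j" (the right-branch condition is stored with i/j swapped),
## predicted, else_class (binary only), oob_error, support, tree, node).

#' Extract candidate rules from a rank forest
#'
#' One rule per terminal node of every tree: the conjunction of pair-order
#' conditions on the root-to-leaf path, the leaf's majority class, and the
#' out-of-bag misclassification error of that prediction among the source
#' tree's OOB samples matching the conjunction.  Leaves matched by no OOB
#' sample get error 1 and support 0, so they rank last.
#'
#' With `max_length`, paths are truncated at that depth: every node at
#' depth `max_length` (and every shallower leaf) becomes a rule with its
#' own majority class.  Deep forests memorise, so their full leaf paths
#' are long, narrow conjunctions whose OOB error estimates rest on a
#' handful of samples; truncation yields short, well-supported rules that
#' generalise — the recommended setting for interpretation is 2 or 3.
#'
#' @param object A [rank_forest()] fit with `keep_data = TRUE`.
#' @param max_length Maximum number of conditions per rule (`NULL`, the
#'   default, extracts full leaf paths, so rule length is capped by the
#'   forest's `max_depth`).
#' @return Object of class `"rank_rules"`: a list of rules with a
#'   data-frame view available via `as.data.frame()`.
#' @seealso [select_rules()], [predict.rank_rules()], [format_rule()]
#' @export
extract_rules <- function(object, max_length = NULL) {
  stopifnot(inherits(object, "rank_forest"))
  if (is.null(object$x))
    pt_stop("forest was fitted with keep_data = FALSE",
            "pairtree_param_error")
  if (!is.null(max_length) && max_length < 1L)
    pt_stop("max_length must be >= 1", "pairtree_param_error")
  fl <- object$flat
  X <- object$x
  yint <- as.integer(object$y)
  ids <- object$train_node_ids            # samples x trees terminal ids
  oob <- !object$in_bag
  rules <- vector("list", length(fl$var_i))
  r <- 0L
  for (m in seq_len(object$n_trees)) {
    nodes <- which(fl$tree_id == m)
    root <- fl$roots[m]
    ## parent/direction links within this tree
    parent <- integer(length(fl$var_i))
    side <- integer(length(fl$var_i))     # 1 = left (<=), 2 = right (>)
    for (v in nodes[fl$var_i[nodes] > 0L]) {
      parent[fl$left[v]] <- v; side[fl$left[v]] <- 1L
      parent[fl$right[v]] <- v; side[fl$right[v]] <- 2L
    }
    oob_s <- which(oob[, m])
    if (is.null(max_length)) {
      rule_nodes <- nodes[fl$var_i[nodes] == 0L]
      leaf_of_oob <- ids[oob_s, m]
    } else {
      rule_nodes <- nodes[fl$depth[nodes] == max_length |
                          (fl$depth[nodes] < max_length &
                           fl$var_i[nodes] == 0L)]
      ## route OOB samples at most max_length steps from the root
      leaf_of_oob <- rep(root, length(oob_s))
      for (step in seq_len(max_length)) {
        active <- which(fl$var_i[leaf_of_oob] > 0L)
        if (!length(active)) break
        v <- leaf_of_oob[active]
        xi <- X[cbind(oob_s[active], fl$var_i[v])]
        xj <- X[cbind(oob_s[active], fl$var_j[v])]
        leaf_of_oob[active] <- ifelse(xi <= xj, fl$left[v], fl$right[v])
      }
    }
    for (t in rule_nodes) {
      ## walk up to the root collecting conditions
      cond <- NULL
      v <- t
      while (v != root) {
        p <- parent[v]
        cond <- rbind(if (side[v] == 1L) c(fl$var_i[p], fl$var_j[p])
                      else c(fl$var_j[p], fl$var_i[p]), cond)
        v <- p
      }
      if (is.null(cond)) next                     # depth-0 tree: no rule
      pred <- object$node_class[t]
      match_s <- oob_s[leaf_of_oob == t]
      support <- length(match_s)
      wrong <- sum(yint[match_s] != pred)
      err <- if (support == 0L) 1 else wrong / support
      ## Laplace-smoothed error: ranks a well-supported clean rule above a
      ## tiny-support one with the same raw error (m-estimate, m = 2)
      score <- if (support == 0L) 1 else (wrong + 1) / (support + 2)
      r <- r + 1L
      rules[[r]] <- list(
        cond = cond, predicted = pred,
        else_class = if (length(object$classes) == 2L)
          3L - pred else NA_integer_,
        oob_error = err, score = score, support = support,
        tree = m, node = t)
    }
  }
  rules <- rules[seq_len(r)]
  structure(rules, class = "rank_rules", classes = object$classes,
            gene_names = object$gene_names,
            majority_class = which.max(tabulate(yint,
                                                length(object$classes))))
}

.rule_key <- function(rule) {
  cond <- rule$cond[order(rule$cond[, 1L], rule$cond[, 2L]), , drop = FALSE]
  paste(cond[, 1L], cond[, 2L], sep = "<", collapse = "&")
}

#' Rank and select a compact rule set
#'
#' Rules are sorted by ascending out-of-bag error — Laplace-smoothed as
#' `(wrong + 1) / (support + 2)`, so that among clean rules the
#' well-supported ones rank first and zero-support leaves rank last —
#' with remaining ties broken by higher OOB support, then fewer
#' conditions, then source (tree, node) order.  Duplicate condition sets
#' are collapsed to their best-ranked representative and the top `k`
#' returned.  For binary problems an odd `k` avoids voting ties.
#'
#' @param rules A [extract_rules()] result.
#' @param k Number of rules requested; if it exceeds the number of distinct
#'   rules, all are returned with a warning.
#' @return A `"rank_rules"` object of (at most) `k` rules.
#' @export
select_rules <- function(rules, k = 5L) {
  stopifnot(inherits(rules, "rank_rules"))
  if (k < 1L) pt_stop("k must be >= 1", "pairtree_param_error")
  err <- vapply(rules, `[[`, 0, "score")
  sup <- vapply(rules, `[[`, 0, "support")
  len <- vapply(rules, function(r) nrow(r$cond), 0)
  src <- order(vapply(rules, `[[`, 0, "tree"), vapply(rules, `[[`, 0, "node"))
  rank_in_src <- integer(length(rules)); rank_in_src[src] <- seq_along(src)
  o <- order(err, -sup, len, rank_in_src)
  keys <- vapply(rules[o], .rule_key, "")
  o <- o[!duplicated(keys)]
  if (k > length(o)) {
    warning(sprintf("only %d distinct rules available (requested %d)",
                    length(o), k))
    k <- length(o)
  }
  structure(rules[o[seq_len(k)]], class = "rank_rules",
            classes = attr(rules, "classes"),
            gene_names = attr(rules, "gene_names"),
            majority_class = attr(rules, "majority_class"))
}

## Logical matrix samples x rules of conjunction satisfaction.
## Matching uses the same convention as tree routing: a stored condition
## (i, j) means this branch took x_i <= x_j.
.rules_match <- function(rules, X) {
  vapply(rules, function(r) {
    m <- rep(TRUE, nrow(X))
    for (q in seq_len(nrow(r$cond)))
      m <- m & (X[, r$cond[q, 1L]] <= X[, r$cond[q, 2L]])
    m
  }, logical(nrow(X)))
}

#' Classify with a rule set
#'
#' Every rule matched by a sample votes for its predicted class; an
#' unmatched binary rule votes for its else-class.  The majority wins, ties
#' break to the lowest class index, and a sample matching nothing (possible
#' only with three or more classes) receives the training-majority class.
#' The forest itself remains the recommended predictor: rules exist for
#' interpretation, and this classifier serves to validate their quality.
#'
#' @param object A `"rank_rules"` set (usually from [select_rules()]).
#' @param newdata Matrix or [rank_data].
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.rank_rules <- function(object, newdata, ...) {
  if (length(object) == 0L)
    pt_stop("empty rule set", "pairtree_param_error")
  X <- .newdata_matrix(newdata, attr(object, "gene_names"))
  classes <- attr(object, "classes")
  K <- length(classes)
  mm <- matrix(.rules_match(object, X), nrow(X))
  votes <- matrix(0L, nrow(X), K)
  for (r in seq_along(object)) {
    pc <- object[[r]]$predicted
    votes[, pc] <- votes[, pc] + mm[, r]
    ec <- object[[r]]$else_class
    if (!is.na(ec)) votes[, ec] <- votes[, ec] + !mm[, r]
  }
  none <- rowSums(votes) == 0L
  votes[none, attr(object, "majority_class")] <- 1L
  factor(classes[max.col(votes, ties.method = "first")], levels = classes)
}

#' Format a rule as human-readable text
#'
#' Renders e.g. `"IF GENE1 < GENE2 AND GENE3 < GENE4 THEN A ELSE B"` using
#' gene names.  A stored condition (i, j) (branch `x_i <= x_j`) prints as
#' `i < j`, so right branches appear with their genes swapped; [parse_rule()]
#' also accepts the `>` spelling.  Ties, routed left, are glossed by `<`.
#'
#' @param rule One element of a `"rank_rules"` object.
#' @param gene_names Gene names indexed by the rule's conditions.
#' @param classes Class labels indexed by `predicted` / `else_class`.
#' @return A single string.
#' @export
format_rule <- function(rule, gene_names, classes) {
  conds <- apply(rule$cond, 1L, function(p)
    paste(gene_names[p[1L]], "<", gene_names[p[2L]]))
  s <- paste("IF", paste(conds, collapse = " AND "),
             "THEN", classes[rule$predicted])
  if (!is.na(rule$else_class))
    s <- paste(s, "ELSE", classes[rule$else_class])
  s
}

#' Parse a formatted rule string back into a rule object
#'
#' Inverse of [format_rule()] (modulo the unstated OOB fields): accepts the
#' `IF ... AND ... THEN ... [ELSE ...]` syntax with `<` / `>` conditions.
#'
#' @param text One rule string.
#' @param gene_names,classes Vocabularies used to resolve names.
#' @return A rule list with `cond`, `predicted`, `else_class`.
#' @export
parse_rule <- function(text, gene_names, classes) {
  m <- regmatches(text, regexec(
    "^\\s*IF\\s+(.+?)\\s+THEN\\s+(\\S+)(?:\\s+ELSE\\s+(\\S+))?\\s*$", text))[[1]]
  if (length(m) == 0L)
    pt_stop("cannot parse rule text", "pairtree_rule_parse_error")
  conds <- strsplit(m[2], "\\s+AND\\s+")[[1]]
  cond <- t(vapply(conds, function(cs) {
    p <- strsplit(trimws(cs), "\\s*([<>])\\s*")[[1]]
    idx <- match(p, gene_names)
    if (anyNA(idx) || length(idx) != 2L)
      pt_stop(sprintf("unknown gene in condition '%s'", cs),
              "pairtree_rule_parse_error")
    if (grepl(">", cs)) rev(idx) else idx
  }, integer(2)))
  dimnames(cond) <- NULL
  pred <- match(m[3], classes)
  els <- if (length(m) >= 4L && nzchar(m[4])) match(m[4], classes)
         else NA_integer_
  if (is.na(pred))
    pt_stop("unknown class in rule text", "pairtree_rule_parse_error")
  list(cond = cond, predicted = pred, else_class = els,
       oob_error = NA_real_, score = NA_real_, support = NA_integer_,
       tree = NA_integer_, node = NA_integer_)
}

#' @export
print.rank_rules <- function(x, max_rules = 10L, ...) {
  gn <- attr(x, "gene_names"); cl <- attr(x, "classes")
  cat(sprintf("%d classification rule(s) from rank-based trees\n",
              length(x)))
  for (r in head(seq_along(x), max_rules))
    cat(sprintf("%2d. %s   [OOB error %.3f, support %d]\n", r,
                format_rule(x[[r]], gn, cl),
                x[[r]]$oob_error, x[[r]]$support))
  if (length(x) > max_rules)
    cat(sprintf("... and %d more\n", length(x) - max_rules))
  invisible(x)
}

#' @export
as.data.frame.rank_rules <- function(x, ...) {
  gn <- attr(x, "gene_names"); cl <- attr(x, "classes")
  data.frame(
    rule = vapply(x, format_rule, "", gene_names = gn, classes = cl),
    n_conditions = vapply(x, function(r) nrow(r$cond), 0),
    predicted = cl[vapply(x, `[[`, 0L, "predicted")],
    oob_error = vapply(x, `[[`, 0, "oob_error"),
    score = vapply(x, `[[`, 0, "score"),
    support = vapply(x, `[[`, 0, "support"),
    tree = vapply(x, `[[`, 0, "tree"),
    stringsAsFactors = FALSE)
}
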