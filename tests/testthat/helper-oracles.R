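# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately written from first principles (tables, two-pass
# sums, numeric optimisation) and never call the code paths they check.

# weighted daughter Gini impurity of a candidate split, from counts
oracle_weighted_gini <- function(left_counts, total_counts) {
  n <- sum(total_counts)
  nl <- sum(left_counts)
  right <- total_counts - left_counts
  gini <- function(cnt) {
    if (sum(cnt) == 0) return(0)
    p <- cnt / sum(cnt)
    1 - sum(p^2)
  }
  (nl / n) * gini(left_counts) + ((n - nl) / n) * gini(right)
}

# exhaustive best-pair search by direct impurity minimisation
oracle_best_pair <- function(X, y, idx, genes) {
  y <- as.integer(as.factor(y))
  K <- max(y)
  genes <- sort(genes)
  n <- length(idx)
  total <- tabulate(y[idx], K)
  parent_gini <- 1 - sum((total / n)^2)
  best <- NULL
  best_imp <- parent_gini - 1e-12
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (b <= a) next
      i <- genes[a]; j <- genes[b]
      go_left <- X[idx, i] <= X[idx, j]
      if (!any(go_left) || all(go_left)) next
      left <- tabulate(y[idx][go_left], K)
      imp <- oracle_weighted_gini(left, total)
      if (imp < best_imp - 1e-15) {  # strict; ties keep first (lowest pair)
        best_imp <- imp
        best <- c(i = i, j = j)
      }
    }
  }
  best
}

# two-pass within-daughter sum of squared deviations
oracle_sse <- function(z, go_left) {
  ssd <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  ssd(z[go_left]) + ssd(z[!go_left])
}

# golden-section minimiser of a unimodal function on [lo, hi]
oracle_golden_min <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - gr * (b - a); d <- a + gr * (b - a)
  }
  (a + b) / 2
}

logit_cost_ref <- function(y, f) log(1 + exp(-2 * y * f))

# random mixed-label nodes filtered to near-convergence (the exact node
# optimum close to 0), the regime where a single Newton step is accurate
near_converged_nodes <- function(n_nodes, gamma_cut = 0.02) {
  out <- list()
  while (length(out) < n_nodes) {
    n <- sample(6:16, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    f <- y * runif(n, 0.3, 2)
    gstar <- oracle_golden_min(function(g) sum(logit_cost_ref(y, f + g)),
                               -4, 4, tol = 1e-10)
    if (abs(gstar) > gamma_cut) next
    out[[length(out) + 1L]] <- list(y = y, f = f, gstar = gstar)
  }
  out
}

# class separable by a single pair order relation, tie-free
tiny_pair_data <- function(n = 30, P = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * P), n, P)
  colnames(X) <- paste0("g", seq_len(P))
  y <- factor(ifelse(X[, 1] < X[, 2], "A", "B"))
  # ensure both classes present
  if (nlevels(droplevels(y)) < 2) {
    X[1, 1:2] <- c(0.1, 0.9); X[2, 1:2] <- c(0.9, 0.1)
    y <- factor(ifelse(X[, 1] < X[, 2], "A", "B"))
  }
  list(X = X, y = y)
}

# a strictly increasing transform chosen per sample, never the identity
distort_rows <- function(X, seed = 1) {
  set.seed(seed)
  out <- X
  for (s in seq_len(nrow(X))) {
    kind <- s %% 3
    if (kind == 0) out[s, ] <- log1p(X[s, ]) * runif(1, 1, 5)
    else if (kind == 1) out[s, ] <- X[s, ]^runif(1, 0.3, 2) + runif(1)
    else out[s, ] <- exp(X[s, ] / (max(X[s, ]) + 1)) * runif(1, 1, 3)
  }
  out
}

# hand-built rule records for selection/prediction semantics tests
make_rule <- function(cond, predicted, else_class = NA_integer_,
                      oob_error = 0, support = 1, tree = 1L, node = 1L) {
  score <- if (support == 0) 1 else (oob_error * support + 1) / (support + 2)
  list(cond = matrix(cond, ncol = 2, byrow = TRUE), predicted = predicted,
       else_class = else_class, oob_error = oob_error, score = score,
       support = support, tree = tree, node = node)
}

make_rules <- function(rules, classes, gene_names,
                       majority_class = 1L) {
  structure(rules, class = "rank_rules", classes = classes,
            gene_names = gene_names, majority_class = majority_class)
}
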