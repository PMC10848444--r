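## Synthetic expression data with planted within-sample rank structure.
##
## Latent values are i.i.d. log-normal (continuous, so ties are impossible
## unless zero-inflation is requested); class labels are functions of the
## order relations of a few planted gene pairs; optional strictly
## increasing per-sample transforms emulate cross-platform measurement.
## Because labels depend on the data only through pair indicators, any
## monotone distortion leaves the planted signal — and every rank-based
## classifier — exactly unchanged, which is the property the generator
## exists to exercise.

.enforce_order <- function(values, i, j, smaller_first) {
  a <- values[i]; b <- values[j]
  lo <- min(a, b); hi <- max(a, b)
  if (smaller_first) { values[i] <- lo; values[j] <- hi }
  else { values[i] <- hi; values[j] <- lo }
  values
}

## Deterministic class patterns over the planted pairs for K >= 3: class k
## satisfies the relations of its own contiguous block of pairs and
## violates the rest, giving well-separated binary codes.
.class_patterns <- function(K, n_pairs) {
  blocks <- floor(seq(0, K, length.out = n_pairs + 1L)[-1] - 1e-9)
  t(vapply(seq_len(K) - 1L, function(k) as.integer(blocks == k),
           integer(n_pairs)))
}

#' Simulate expression data with planted rank structure
#'
#' Generates a samples x genes matrix whose class labels are functions of
#' planted pairwise order relations, the testbed for every rank-based
#' method in the package.
#'
#' Label mechanisms:
#' * `rule = "single"` (K = 2): one planted pair; class 1 samples satisfy
#'   `x_i < x_j`, class 2 samples violate it.  A depth-1 tree is Bayes
#'   optimal.
#' * `rule = "conjunction"` (K = 2): class 1 satisfies *all* planted
#'   relations; class 2 satisfies each relation independently with
#'   probability `null_agreement`, conditioned on not satisfying all —
#'   the violations are correlated across pairs, as reversals of co-regulated
#'   markers are in practice.  No single pair separates the classes;
#'   conjunctions do.
#' * K >= 3: each class deterministically satisfies its own block of
#'   planted relations and violates the others.
#'
#' Label noise then reassigns exactly `round(flip_noise * n_k)` randomly
#' chosen samples of every class to another class, so the Bayes accuracy is
#' `1 - flip_noise` and two-class balance stays exact.  Distortions are
#' applied last and are strictly increasing per sample, so they change
#' values but no pair indicator.
#'
#' @param n_samples Number of samples (split across classes as evenly as
#'   the integers allow, exactly).
#' @param n_genes Number of genes P.
#' @param n_classes Number of classes K.
#' @param n_pairs Number of planted pairs (used when `pairs` is `NULL`;
#'   they occupy genes 1..2*n_pairs, disjointly).
#' @param pairs Optional explicit two-column matrix of planted pairs
#'   (disjoint genes required for the conjunction mechanism).
#' @param rule `"conjunction"` (default) or `"single"`.
#' @param null_agreement Probability that a class-2 sample satisfies any
#'   one planted relation (conjunction rule); default 0.10 — the classes
#'   mostly reverse the planted orders, the "relative expression
#'   reversal" premise of top-scoring-pair classification.
#' @param flip_noise Label-flip probability in `[0, 0.5)`.
#' @param distortion `"none"`, `"monotone"` (an independent strictly
#'   increasing power-affine map per sample) or `"platform"` (samples fall
#'   in two blocks with very different monotone maps, a log-like and a
#'   power-like one, mimicking microarray vs sequencing scales).
#' @param tie_rate Fraction of entries set to 0 *after* planting, creating
#'   ties and eroding planted relations — the zero-inflation stress test.
#' @param seed Integer seed; fixed seed gives a bit-identical dataset.
#' @return List with `data` (a [rank_data]), and `truth`: planted `pairs`
#'   (gene-name matrix), class `patterns`, the `rule`, `flip_noise`,
#'   `bayes_accuracy`, and the pre-flip `clean_labels`.
#' @examples
#' sim <- simulate_rank_data(n_samples = 40, n_genes = 8, n_pairs = 1,
#'                           rule = "single", seed = 1)
#' table(sim$data$labels)
#' @export
simulate_rank_data <- function(n_samples = 200L, n_genes = 50L,
                               n_classes = 2L, n_pairs = 5L, pairs = NULL,
                               rule = c("conjunction", "single"),
                               null_agreement = 0.10, flip_noise = 0,
                               distortion = c("none", "monotone",
                                              "platform"),
                               tie_rate = 0, seed = NULL) {
  rule <- match.arg(rule)
  distortion <- match.arg(distortion)
  if (flip_noise < 0 || flip_noise >= 0.5)
    pt_stop("flip_noise must lie in [0, 0.5)", "pairtree_param_error")
  if (tie_rate < 0 || tie_rate >= 1)
    pt_stop("tie_rate must lie in [0, 1)", "pairtree_param_error")
  if (rule == "single") n_pairs <- 1L
  if (is.null(pairs))
    pairs <- cbind(seq_len(n_pairs) * 2L - 1L, seq_len(n_pairs) * 2L)
  pairs <- as.matrix(pairs)
  n_pairs <- nrow(pairs)
  if (max(pairs) > n_genes)
    pt_stop("more planted pairs than gene slots", "pairtree_param_error")
  if (rule == "conjunction" && anyDuplicated(as.vector(pairs)))
    pt_stop("planted pairs must be disjoint under the conjunction rule",
            "pairtree_param_error")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)

  K <- n_classes
  ## exact class balance, then random order
  y <- sample(rep_len(seq_len(K), n_samples))
  ## Per-gene baseline levels: the two genes of a planted pair share one,
  ## and baselines are spread widely across pairs (genes span orders of
  ## magnitude, as expression does), so that only within-pair order — not
  ## comparisons across pairs — carries the planted class signal.
  ## Baselines are population parameters, fixed by gene index (a seed-free
  ## low-discrepancy sequence), so that independently simulated datasets
  ## with the same dimensions come from the same population.
  offsets <- (seq_len(n_pairs) - (n_pairs + 1) / 2) * 4
  u <- (seq_len(n_genes) * 0.6180339887498949) %% 1
  meanlog <- log(100) + (min(offsets) - 1) + u * (diff(range(offsets)) + 2)
  for (q in seq_len(n_pairs)) meanlog[pairs[q, ]] <- log(100) + offsets[q]
  X <- matrix(rlnorm(n_samples * n_genes, sdlog = 1),
              n_samples, n_genes)
  X <- sweep(X, 2L, exp(meanlog), `*`)
  patterns <- if (K == 2L) rbind(rep(1L, n_pairs), rep(0L, n_pairs))
              else .class_patterns(K, n_pairs)

  ## Class-2 violation patterns (conjunction rule): the number of satisfied
  ## relations is Binomial(n_pairs, null_agreement) conditioned on not all,
  ## and which relations are satisfied follows a balanced rotation, so each
  ## planted relation carries the same empirical signal strength.
  sat_count <- integer(n_pairs)
  for (s in seq_len(n_samples)) {
    ind <- if (K == 2L && rule == "conjunction" && y[s] == 2L) {
      repeat {
        k <- sum(runif(n_pairs) < null_agreement)
        if (k < n_pairs) break
      }
      draw <- integer(n_pairs)
      if (k > 0L) {
        pick <- order(sat_count + runif(n_pairs))[seq_len(k)]
        draw[pick] <- 1L
        sat_count[pick] <- sat_count[pick] + 1L
      }
      draw
    } else patterns[y[s], ]
    for (q in seq_len(n_pairs))
      X[s, ] <- .enforce_order(X[s, ], pairs[q, 1L], pairs[q, 2L],
                               smaller_first = ind[q] == 1L)
  }

  ## Label noise is stratified: exactly round(flip_noise * n_k) samples of
  ## every class are reassigned to a random other class, so the Bayes
  ## accuracy is 1 - flip_noise and two-class balance stays exact.
  clean <- y
  if (flip_noise > 0) {
    for (cl in seq_len(K)) {
      members <- which(clean == cl)
      nf <- round(flip_noise * length(members))
      if (nf > 0) {
        pick <- sample(members, nf)
        y[pick] <- vapply(pick, function(s)
          if (K == 2L) 3L - clean[s]
          else sample(setdiff(seq_len(K), clean[s]), 1L), 0L)
      }
    }
  }
  if (tie_rate > 0) {
    nz <- round(tie_rate * length(X))
    X[sample.int(length(X), nz)] <- 0
  }
  if (distortion == "monotone") {
    for (s in seq_len(n_samples)) {
      a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 1.5); cc <- runif(1, 0, 10)
      X[s, ] <- a * X[s, ]^b + cc
    }
  } else if (distortion == "platform") {
    block <- seq_len(n_samples) <= n_samples / 2
    X[block, ] <- 10 * log1p(X[block, , drop = FALSE])
    X[!block, ] <- X[!block, , drop = FALSE]^1.5 / 50
  }

  colnames(X) <- sprintf("g%03d", seq_len(n_genes))
  rownames(X) <- sprintf("s%04d", seq_len(n_samples))
  labels <- factor(paste0("C", y), levels = paste0("C", seq_len(K)))
  truth <- list(
    pairs = cbind(gene_i = colnames(X)[pairs[, 1L]],
                  gene_j = colnames(X)[pairs[, 2L]]),
    pair_index = pairs, patterns = patterns, rule = rule,
    null_agreement = if (rule == "conjunction" && K == 2L)
      null_agreement else NA_real_,
    flip_noise = flip_noise, bayes_accuracy = 1 - flip_noise,
    clean_labels = factor(paste0("C", clean),
                          levels = paste0("C", seq_len(K))))
  list(data = rank_data(X, labels), truth = truth)
}

#' The standard planted-pair benchmark dataset
#'
#' The canonical seeded instance used throughout the package's tests and
#' examples: 200 samples (100 per class, K = 2), 50 genes, 5 planted pairs
#' over the first 10 genes, conjunction rule, 5\% label-flip noise.
#' Repeated calls are bit-identical.
#'
#' @return As [simulate_rank_data()]: list with `data` and `truth`.
#' @export
standard_benchmark <- function() {
  simulate_rank_data(n_samples = 200L, n_genes = 50L, n_classes = 2L,
                     n_pairs = 5L, rule = "conjunction",
                     null_agreement = 0.10, flip_noise = 0.05,
                     seed = 20240207L)
}

## Bayes-rule classifier from the generator's ground truth; used to verify
## that the label-generating rule is reachable at accuracy 1 - flip_noise.
.oracle_predict <- function(truth, x) {
  X <- if (inherits(x, "rank_data")) x$values else as.matrix(x)
  ind <- t(apply(X, 1L, function(row)
    as.integer(row[truth$pair_index[, 1L]] <= row[truth$pair_index[, 2L]])))
  ind <- matrix(ind, nrow(X))
  K <- nrow(truth$patterns)
  if (K == 2L && truth$rule %in% c("conjunction", "single")) {
    k <- ifelse(rowSums(ind) == ncol(ind), 1L, 2L)
  } else {
    ham <- vapply(seq_len(K), function(cl)
      rowSums(sweep(ind, 2L, truth$patterns[cl, ], `!=`)), numeric(nrow(X)))
    k <- max.col(-matrix(ham, nrow(X)), ties.method = "first")
  }
  factor(paste0("C", k), levels = paste0("C", seq_len(K)))
}
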