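## Performance measurement: confusion matrix, accuracy, class-balanced
## train/validation/test splits, a replicated benchmark harness, and
## parameter sweeps.

#' Confusion matrix
#'
#' Counts `c_ij` of samples of true class i predicted as class j, with a
#' fixed class order shared by rows and columns.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class order; default the union of observed levels.
#' @return A K x K contingency `table` (truth in rows).
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    pt_stop("truth and predicted must have equal length",
            "pairtree_dimension_error")
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  table(truth = factor(truth, levels = classes),
        predicted = factor(predicted, levels = classes))
}

#' Classification accuracy
#'
#' `ACC = sum_i c_ii / N`, the trace of the confusion matrix over the total
#' count.  Accepts either a confusion matrix or a pair of label vectors.
#'
#' @param truth Confusion matrix (then `predicted` is ignored) or true
#'   labels.
#' @param predicted Predicted labels.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' accuracy(matrix(c(3, 2, 1, 4), 2))          # 0.7
#' accuracy(c("a", "b"), c("a", "a"))          # 0.5
#' @export
accuracy <- function(truth, predicted = NULL) {
  cm <- if (is.matrix(truth) || is.table(truth)) truth
        else confusion_matrix(truth, predicted)
  if (sum(cm) == 0) pt_stop("empty confusion matrix", "pairtree_count_error")
  if (nrow(cm) != ncol(cm))
    pt_stop("confusion matrix must be square", "pairtree_dimension_error")
  sum(diag(as.matrix(cm))) / sum(cm)
}

## Largest-remainder apportionment of n_c samples to the split fractions.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    o <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[o] <- base[o] + 1
  }
  as.integer(base)
}

#' Class-balanced train/validation/test split
#'
#' Partitions samples within each class according to the fractions
#' (largest-remainder rounding, so realised counts are within one sample of
#' the target), yielding disjoint, exhaustive index sets.  Optionally the
#' data are first resampled within class to approximately equal class sizes
#' (`n_i / N ~ 1/K`), by subsampling to the smallest class or by
#' bootstrapping to `N / K`; resampled splits are then balanced but no
#' longer exhaustive (and under bootstrap an index can repeat within a set,
#' never across sets).
#'
#' @param y Class label per sample.
#' @param fractions Three fractions summing to 1 (train, validation, test).
#' @param rebalance `"none"` (default), `"subsample"` or `"bootstrap"`.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
balanced_split <- function(y, fractions = c(0.70, 0.15, 0.15),
                           rebalance = c("none", "subsample", "bootstrap")) {
  rebalance <- match.arg(rebalance)
  y <- as.factor(y)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    pt_stop("fractions must be three numbers summing to 1",
            "pairtree_param_error")
  tab <- table(y)
  if (any(tab < 3L))
    pt_stop(sprintf("class '%s' has fewer than 3 samples",
                    names(tab)[which.min(tab)]),
            "pairtree_class_count_error")
  sets <- list(train = integer(0), validation = integer(0),
               test = integer(0))
  target <- switch(rebalance,
                   none = NA_integer_,
                   subsample = min(tab),
                   bootstrap = as.integer(round(length(y) / nlevels(y))))
  for (cl in levels(y)) {
    members <- which(y == cl)
    members <- switch(rebalance,
      none = sample(members),
      subsample = sample(members)[seq_len(target)],
      bootstrap = sample(members, target, replace = TRUE))
    cnt <- .apportion(length(members), fractions)
    sets$train <- c(sets$train, members[seq_len(cnt[1L])])
    sets$validation <- c(sets$validation,
                         members[cnt[1L] + seq_len(cnt[2L])])
    sets$test <- c(sets$test,
                   members[cnt[1L] + cnt[2L] + seq_len(cnt[3L])])
  }
  lapply(sets, sort)
}

## Fold labels balanced within class, for held-out loss estimation.
.balanced_folds <- function(y, n_folds) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    members <- sample(which(y == cl))
    folds[members] <- rep_len(seq_len(n_folds), length(members))
  }
  folds
}

.fit_method <- function(method, X, y, config, ...) {
  dots <- list(...)
  args <- c(list(x = X, y = y), config, dots[setdiff(names(dots),
                                                     names(config))])
  switch(method,
    forest = do.call(rank_forest, args),
    boost = do.call(rank_boost, args),
    majority = structure(list(level = names(which.max(table(y))),
                              classes = levels(as.factor(y))),
                         class = "pt_majority"),
    pt_stop(sprintf("unknown method '%s'", method), "pairtree_param_error"))
}

#' @export
predict.pt_majority <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "rank_data")) nrow(newdata$values)
       else nrow(as.matrix(newdata))
  factor(rep(object$level, n), levels = object$classes)
}

#' Replicated class-balanced benchmark
#'
#' For each replicate: draw a class-balanced 70/15/15 train/validation/test
#' split, fit each method on the training set for every configuration in
#' its tuning grid, pick the configuration with the best validation
#' accuracy, and record that model's test accuracy.  Tuning data and test
#' data are disjoint by construction.  Method failures are recorded per
#' replicate, not fatal.
#'
#' @param x A [rank_data] or samples x genes matrix.
#' @param y Class labels.
#' @param methods Subset of `c("forest", "boost", "majority")` (the last is
#'   a chance-level baseline scoring ~ 1/K under class balance).
#' @param n_reps Number of replicates (50 in a full run; reduce for quick
#'   checks).
#' @param fractions Split fractions.
#' @param grids Named list of tuning data frames (one row per candidate
#'   configuration, columns are fitter arguments).  Methods without a grid
#'   use their defaults, i.e. a single configuration.
#' @param rebalance Passed to [balanced_split()].
#' @param seed Integer seed for the whole procedure.
#' @param ... Fixed arguments passed to every fit (e.g. `n_trees`).
#' @return Object of class `"rank_benchmark"`: a data frame with one row
#'   per (replicate, method) holding the test `accuracy` and chosen
#'   `config`; `summary()` gives per-method mean and SD.
#' @export
replicate_benchmark <- function(x, y = NULL,
                                methods = c("forest", "boost"),
                                n_reps = 50L,
                                fractions = c(0.70, 0.15, 0.15),
                                grids = NULL,
                                rebalance = "none",
                                seed = NULL, ...) {
  d <- .xy_input(x, y)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)
  rows <- list()
  for (r in seq_len(n_reps)) {
    sp <- balanced_split(d$y, fractions, rebalance = rebalance)
    for (method in methods) {
      grid <- grids[[method]]
      if (is.null(grid)) grid <- data.frame(row.names = 1L)
      res <- tryCatch({
        best <- NULL; best_val <- -Inf; best_cfg <- ""
        for (g in seq_len(max(1L, nrow(grid)))) {
          config <- if (ncol(grid)) lapply(grid, `[[`, g) else list()
          fit <- .fit_method(method, d$X[sp$train, , drop = FALSE],
                             d$y[sp$train], config, ...)
          val_acc <- if (length(sp$validation))
            mean(predict(fit, d$X[sp$validation, , drop = FALSE]) ==
                 d$y[sp$validation]) else NA_real_
          if (is.na(val_acc) || val_acc > best_val) {
            best <- fit; best_val <- val_acc
            best_cfg <- paste(names(config), unlist(config),
                              sep = "=", collapse = ",")
          }
        }
        acc <- mean(predict(best, d$X[sp$test, , drop = FALSE]) ==
                    d$y[sp$test])
        list(accuracy = acc, config = best_cfg, error = NA_character_)
      }, error = function(e) list(accuracy = NA_real_, config = "",
                                  error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, method = method, accuracy = res$accuracy,
                   config = res$config, error = res$error,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rank_benchmark", "data.frame")
  out
}

#' @export
summary.rank_benchmark <- function(object, ...) {
  agg <- aggregate(accuracy ~ method, data = object,
                   FUN = function(a) c(mean = mean(a), sd = sd(a),
                                       n = length(a)))
  out <- data.frame(method = agg$method,
                    mean_accuracy = agg$accuracy[, "mean"],
                    sd_accuracy = agg$accuracy[, "sd"],
                    n_reps = agg$accuracy[, "n"])
  out
}

#' @export
print.rank_benchmark <- function(x, ...) {
  cat(sprintf("replicated benchmark: %d replicate(s) x %d method(s)\n",
              max(x$rep), length(unique(x$method))))
  print(summary(x))
  invisible(x)
}

#' Sweep tuning parameters over a grid
#'
#' Refits a method across a parameter grid with repeated class-balanced
#' splits and reports mean and SD of test accuracy per grid point — the
#' harness behind learning-rate, tree-number, depth, node-size and
#' candidate-set robustness curves.
#'
#' @param x,y Data as in [replicate_benchmark()].
#' @param method `"forest"` or `"boost"`.
#' @param grid Data frame; columns are fitter arguments, one row per
#'   configuration.
#' @param n_reps Replicates per grid point.
#' @param fractions Split fractions (validation unused here).
#' @param seed Integer seed.
#' @param ... Fixed fitter arguments.
#' @return The grid with `mean_accuracy` and `sd_accuracy` columns
#'   appended.
#' @export
parameter_sweep <- function(x, y = NULL, method = c("forest", "boost"),
                            grid, n_reps = 5L,
                            fractions = c(0.70, 0.15, 0.15),
                            seed = NULL, ...) {
  method <- match.arg(method)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    pt_stop("grid must be a non-empty data frame", "pairtree_param_error")
  d <- .xy_input(x, y)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  } else if (is.null(.save_rng())) set.seed(NULL)
  splits <- lapply(seq_len(n_reps), function(r)
    balanced_split(d$y, fractions))
  acc <- matrix(NA_real_, nrow(grid), n_reps)
  for (g in seq_len(nrow(grid))) {
    config <- lapply(grid, `[[`, g)
    for (r in seq_len(n_reps)) {
      sp <- splits[[r]]
      tr <- c(sp$train, sp$validation)
      fit <- .fit_method(method, d$X[tr, , drop = FALSE], d$y[tr],
                         config, ...)
      acc[g, r] <- mean(predict(fit, d$X[sp$test, , drop = FALSE]) ==
                        d$y[sp$test])
    }
  }
  out <- cbind(grid,
               mean_accuracy = rowMeans(acc),
               sd_accuracy = apply(acc, 1L, sd))
  rownames(out) <- NULL
  out
}
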