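## Dataset container and delimited-text IO.
##
## The canonical layout is samples x genes because every computation in the
## package is within-sample: a split only ever asks whether x_i <= x_j inside
## one profile.  Values may be on any positive measurement scale (raw counts,
## log intensities, FPKM, ...); only their within-sample order is ever used.

pt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pairtree_error")))
}

#' Expression dataset with class labels
#'
#' Bundles a numeric samples x genes matrix with one class label per sample.
#' This is the single input object of the package.  Values are validated once
#' here; downstream fitters assume a well-formed object.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.  Column
#'   names are the gene names (required, unique, non-empty); row names are
#'   sample ids (generated when absent).  Missing values are an error: rank
#'   comparisons are undefined for them.
#' @param labels Class label per sample (factor or coercible); at least two
#'   distinct classes, each with at least one sample.
#' @return An object of class `"rank_data"`: a list with elements `values`
#'   (the matrix) and `labels` (a factor).
#' @examples
#' x <- matrix(rlnorm(20), 4, 5, dimnames = list(NULL, paste0("g", 1:5)))
#' d <- rank_data(x, c("A", "A", "B", "B"))
#' d
#' @export
rank_data <- function(values, labels) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values))
    pt_stop("'values' must be a numeric matrix", "pairtree_type_error")
  if (anyNA(values))
    pt_stop("expression matrix contains missing values",
            "pairtree_missing_value_error")
  gn <- colnames(values)
  if (is.null(gn) || any(!nzchar(gn)))
    pt_stop("all genes must have non-empty names", "pairtree_gene_name_error")
  if (anyDuplicated(gn))
    pt_stop(sprintf("duplicate gene names: %s",
                    paste(unique(gn[duplicated(gn)]), collapse = ", ")),
            "pairtree_duplicate_gene_error")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    pt_stop("duplicate sample ids", "pairtree_duplicate_sample_error")
  if (length(labels) != nrow(values))
    pt_stop(sprintf("%d labels supplied for %d samples",
                    length(labels), nrow(values)),
            "pairtree_label_length_error")
  if (anyNA(labels))
    pt_stop("labels contain missing entries", "pairtree_unknown_label_error")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    pt_stop("need at least two classes", "pairtree_class_count_error")
  structure(list(values = values, labels = labels), class = "rank_data")
}

#' @export
print.rank_data <- function(x, ...) {
  cat(sprintf("rank_data: %d samples x %d genes, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.rank_data <- function(x) dim(x$values)

#' @export
as.matrix.rank_data <- function(x, ...) x$values

.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix with labels
#'
#' Reads a CSV/TSV table (delimiter auto-detected from the extension) whose
#' first column holds sample ids (or gene ids when `orientation =
#' "genes-in-rows"`) and whose header holds the other dimension's names.
#' Labels come either from a column of the table (`label_column`) or from a
#' companion file with one label per line (`labels`), in sample order.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples-in-rows"` (default) or `"genes-in-rows"`;
#'   the latter is transposed to the canonical samples x genes layout.
#' @param labels Path to a one-label-per-line file, or a vector of labels.
#' @param label_column Name of a column of the table containing the labels
#'   (only for samples-in-rows tables).
#' @param sep Field separator; overrides extension-based detection.
#' @return A [rank_data] object.
#' @details Distinct error conditions are signalled for ragged rows
#'   (`pairtree_ragged_row_error`), missing cells
#'   (`pairtree_missing_value_error`), duplicate gene names
#'   (`pairtree_duplicate_gene_error`) and missing/unknown labels
#'   (`pairtree_unknown_label_error`).
#' @export
read_expression <- function(path,
                            orientation = c("samples-in-rows", "genes-in-rows"),
                            labels = NULL, label_column = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- .sep_for(path, sep)
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L)
    pt_stop(sprintf("ragged rows in '%s': field counts %s", path,
                    paste(unique(nf), collapse = "/")),
            "pairtree_ragged_row_error")
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
  lab <- NULL
  if (!is.null(label_column)) {
    if (orientation != "samples-in-rows")
      pt_stop("label_column requires samples-in-rows orientation",
              "pairtree_orientation_error")
    if (!label_column %in% colnames(tab))
      pt_stop(sprintf("label column '%s' not found", label_column),
              "pairtree_unknown_label_error")
    lab <- tab[[label_column]]
    tab <- tab[, setdiff(colnames(tab), label_column), drop = FALSE]
  } else if (!is.null(labels)) {
    lab <- if (is.character(labels) && length(labels) == 1L &&
               file.exists(labels)) readLines(labels) else labels
  } else {
    pt_stop("supply labels via 'labels' or 'label_column'",
            "pairtree_unknown_label_error")
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  if (anyNA(m))
    pt_stop(sprintf("missing or non-numeric cells in '%s'", path),
            "pairtree_missing_value_error")
  if (orientation == "genes-in-rows") m <- t(m)
  rank_data(m, lab)
}

#' Write an expression dataset as delimited text
#'
#' Inverse of [read_expression()]: writes the samples x genes table with a
#' leading sample-id column, plus (optionally) the labels either as an extra
#' column or as a companion one-label-per-line file.  Full `\%.17g` precision
#' is used so a read/write round trip preserves values exactly.
#'
#' @param x A [rank_data] object.
#' @param path Output file (`.csv` writes commas, anything else tabs).
#' @param labels_path If non-`NULL`, labels go to this file; otherwise they
#'   are appended as a `class` column.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "rank_data"))
  sep <- .sep_for(path)
  df <- as.data.frame(format(x$values, digits = 17, trim = TRUE,
                             scientific = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(id = rownames(x$values), df)
  if (is.null(labels_path)) {
    df$class <- as.character(x$labels)
  } else {
    writeLines(as.character(x$labels), labels_path)
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.resolve_pairs <- function(pairs, gene_names) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, function(p) p[1:2]))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L)
    pt_stop("pairs must have two columns (i, j)", "pairtree_pair_error")
  pairs <- pairs[, 1:2, drop = FALSE]
  if (is.character(pairs)) {
    idx <- match(pairs, gene_names)
    if (anyNA(idx))
      pt_stop(sprintf("unknown gene names in pairs: %s",
                      paste(unique(pairs[is.na(idx)]), collapse = ", ")),
              "pairtree_gene_name_error")
    pairs <- matrix(idx, ncol = 2L)
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs < 1L) || any(pairs > length(gene_names)))
    pt_stop("pair index out of range", "pairtree_pair_error")
  if (any(pairs[, 1L] == pairs[, 2L]))
    pt_stop("a pair must involve two distinct genes", "pairtree_pair_error")
  pairs
}

#' Within-sample pair order indicators
#'
#' For each sample s and gene pair (i, j), the indicator of the order
#' relation `x[s, i] <= x[s, j]` — the atomic feature every rank-based tree
#' splits on.  Ties count as `<=` (routed left), a fixed convention that
#' keeps predictions deterministic; see [break_ties()] for the jitter remedy
#' when zeros/ties are abundant.  The matrix is invariant under any strictly
#' increasing transform applied to a sample's row, which is the basis of
#' cross-platform single-sample prediction.
#'
#' @param x A [rank_data] object or numeric samples x genes matrix.
#' @param pairs Two-column matrix (or list of length-2 vectors) of gene
#'   indices or gene names; `i != j` required.
#' @return Integer 0/1 matrix, samples x pairs, with descriptive column names.
#' @export
pair_indicator_matrix <- function(x, pairs) {
  m <- if (inherits(x, "rank_data")) x$values else as.matrix(x)
  gn <- colnames(m)
  if (is.null(gn)) gn <- paste0("g", seq_len(ncol(m)))
  pairs <- .resolve_pairs(pairs, gn)
  ind <- (m[, pairs[, 1L], drop = FALSE] <= m[, pairs[, 2L], drop = FALSE]) * 1L
  dimnames(ind) <- list(rownames(m),
                        paste0(gn[pairs[, 1L]], "<=", gn[pairs[, 2L]]))
  ind
}

#' Break ties by seeded jitter
#'
#' Rank-pair splits are weakened when many values tie (e.g. zero-inflated
#' single-cell counts): the fixed ties-left convention then routes whole
#' blocks of samples one way.  Adding a small amount of seeded uniform noise
#' breaks ties while leaving all strict orderings intact whenever `amount`
#' is below the smallest non-zero gap.
#'
#' @param x A [rank_data] object or numeric matrix.
#' @param amount Upper bound of the added `U(0, amount)` noise.
#' @param seed Integer seed making the jitter reproducible.
#' @return Object of the same type as `x` with jittered values.
#' @export
break_ties <- function(x, amount = 1e-6, seed = 1L) {
  m <- if (inherits(x, "rank_data")) x$values else as.matrix(x)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m2 <- m + matrix(runif(length(m), 0, amount), nrow(m), ncol(m))
  if (inherits(x, "rank_data")) {
    x$values <- m2
    x
  } else m2
}

## Save/restore the global RNG state so seeded helpers do not disturb the
## caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## Coerce new data for prediction: reorder named columns to the training
## gene order, or accept unnamed matrices of the right width.
.newdata_matrix <- function(newdata, gene_names) {
  m <- if (inherits(newdata, "rank_data")) newdata$values else
    as.matrix(newdata)
  if (!is.null(colnames(m)) && !identical(colnames(m), gene_names)) {
    idx <- match(gene_names, colnames(m))
    if (anyNA(idx))
      pt_stop("newdata is missing genes used at training time",
              "pairtree_gene_name_error")
    m <- m[, idx, drop = FALSE]
  }
  if (ncol(m) != length(gene_names))
    pt_stop(sprintf("newdata has %d genes, model expects %d",
                    ncol(m), length(gene_names)),
            "pairtree_dimension_error")
  storage.mode(m) <- "double"
  m
}
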