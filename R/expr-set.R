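#' Labeled expression matrix
#'
#' Container for a labeled gene-expression dataset: an N samples x D genes
#' numeric matrix, gene and sample identifiers, and a binary class label per
#' sample. All downstream functions (embedding, selection, evaluation) take
#' this container.
#'
#' @param values numeric matrix, samples in rows and genes in columns (use
#'   [read_expression()] for genes-as-rows delimited files).
#' @param labels vector of per-sample class labels; one or two distinct
#'   values (two are required for supervised embedding and for evaluation).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the column names of `values` or `g1..gD`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the row names of `values` or `s1..sN`.
#' @param impute_missing logical; if `TRUE`, missing values are replaced by
#'   the per-gene mean over non-missing samples. By default missing values
#'   are rejected.
#'
#' @return An object of class `expr_set` with elements `values`, `gene_ids`,
#'   `sample_ids`, `labels`.
#' @export
expr_set <- function(values, labels, gene_ids = NULL, sample_ids = NULL,
                     impute_missing = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 1L || d < 1L) stop("expression matrix must be non-empty")

  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(d))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != d) stop("gene_ids length must equal the number of gene columns")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))

  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must equal the number of sample rows")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")

  if (length(labels) != n) stop("labels length (", length(labels),
                                ") must equal the number of samples (", n, ")")
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not contain missing values")
  nlab <- length(unique(labels))
  if (nlab > 2L) stop("labels must take at most 2 distinct values, found ", nlab)

  if (anyNA(values)) {
    if (!impute_missing) {
      stop("expression matrix contains missing values; set impute_missing = TRUE ",
           "to apply per-gene mean imputation")
    }
    for (j in which(colSums(is.na(values)) > 0L)) {
      v <- values[, j]
      if (all(is.na(v))) stop("gene ", gene_ids[j], " is entirely missing")
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      values[, j] <- v
    }
  }
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")

  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set: ", nrow(x$values), " samples x ", ncol(x$values), " genes\n",
      sep = "")
  tab <- table(x$labels)
  cat("labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

# subset samples (integer/logical index), keeping all genes
subset_samples <- function(x, idx) {
  expr_set(x$values[idx, , drop = FALSE], x$labels[idx],
           gene_ids = x$gene_ids, sample_ids = x$sample_ids[idx])
}

#' Resolve the positive class of a binary label vector
#'
#' Evaluation metrics need a designated positive class (conventionally the
#' tumor/ALL class). When `positive` is `NULL` the lexicographically greater
#' label is taken, with a warning, so results are deterministic.
#'
#' @param labels vector of labels with exactly two distinct values.
#' @param positive the positive class label, or `NULL` for the default.
#' @return character scalar, the positive class.
#' @export
resolve_positive <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) {
    stop("exactly 2 label classes required, found: ",
         paste(lev, collapse = ", "))
  }
  if (is.null(positive)) {
    positive <- lev[2L]
    warning("positive class not specified; using lexicographically greater label '",
            positive, "'", call. = FALSE)
  } else {
    positive <- as.character(positive)
    if (!positive %in% lev) stop("positive class '", positive, "' not among labels")
  }
  positive
}
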